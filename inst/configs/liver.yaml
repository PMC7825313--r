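# liver CT: 3-slice stacks, no augmentation
loss: DC+WCE
ilr: 3.0e-4
epochs: 100
batch_size: 8
input_size: 224
augment: false
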