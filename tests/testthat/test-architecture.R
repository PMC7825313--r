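# Graph construction: shapes, channel arithmetic, parameter accounting.

test_that("configuration invariants are enforced", {
  expect_error(network_config("tmdunet", input_size = 100), "multiple of 16")
  expect_error(network_config("tunet", node_filters = c(16, 16, 32, 64, 128)),
               "strictly increasing")
  expect_error(network_config("tunet", use_msi = TRUE), "tunet")
  expect_error(network_config("tmdunet", dilation_rates = c(2, 1)),
               "three units")
  cfg <- network_config("tmdunet")
  expect_true(cfg$use_msi && cfg$use_dense_skip)
  expect_identical(network_config("unet")$base_filters, 32L)
})

test_that("stem and pyramid have the documented shapes and parameter counts", {
  cfg <- network_config("tmdunet", input_size = 128, input_channels = 1,
                        base_filters = 16)
  m <- build_model(cfg)
  # stem: one 3x3 conv with 16 filters on a 1-channel image -> 160 weights
  expect_identical(dim(m$params$stem_conv$W), c(3L, 3L, 1L, 16L))
  expect_identical(length(m$params$stem_conv$W) + length(m$params$stem_conv$b),
                   160L)
  expect_equal(m$nodes$stem_bn$out_shape, c(128, 128, 16))
  # pyramid levels halve: 64, 32, 16, 8 px, all base_filters channels
  for (j in 1:4)
    expect_equal(m$nodes[[paste0("msi_level", j, "_bn")]]$out_shape,
                 c(128 / 2^j, 128 / 2^j, 16))
})

test_that("a single maximal pixel survives a max-pooling chain", {
  x <- array(0, c(16, 16, 1))
  x[11, 7, 1] <- 5
  for (j in 1:4) {
    r <- tmdunet:::cpp_maxpool2_fwd(x)
    x <- r$out
    expect_equal(max(x), 5)
  }
  expect_identical(dim(x), c(1L, 1L, 1L))
  # constant input stays constant through pooling
  cst <- array(0.7, c(8, 8, 2))
  expect_true(all(tmdunet:::cpp_maxpool2_fwd(cst)$out == 0.7))
})

test_that("encoder channel arithmetic follows the reference connectivity", {
  conv_in <- function(m, layer) dim(m$params[[layer]]$W)[3]
  mt <- build_model(network_config("tunet"))    # 3-channel input
  # node 1: every unit sees the raw image plus its intra-node predecessors
  expect_equal(sapply(1:3, function(i)
    conv_in(mt, paste0("enc_h1_u", i, "_conv1"))), c(3, 19, 35))
  # node 2: unit 1 pooled cross input, unit 2 intra only, unit 3 both
  expect_equal(sapply(1:3, function(i)
    conv_in(mt, paste0("enc_h2_u", i, "_conv1"))), c(16, 32, 80))
  mm <- build_model(network_config("tmdunet"))
  # node 1 adds the 16-channel stem features to every unit
  expect_equal(sapply(1:3, function(i)
    conv_in(mm, paste0("enc_h1_u", i, "_conv1"))), c(19, 35, 51))
  # nodes 2..5: units 1 and 3 add the 16-channel pyramid feature
  expect_equal(sapply(1:3, function(i)
    conv_in(mm, paste0("enc_h2_u", i, "_conv1"))), c(32, 32, 96))
  expect_equal(conv_in(mm, "enc_h5_u1_conv1"), 128 + 16)
})

test_that("decoder channel arithmetic matches plain and dense skips", {
  conv_in <- function(m, layer) dim(m$params[[layer]]$W)[3]
  mt <- build_model(network_config("tunet"))
  # decoder node 1 unit 2: gamma_1^1 (16) + upsampled (16) + chi_1^2 (16)
  expect_equal(conv_in(mt, "dec_h1_u2_conv1"), 48)
  # unit 1 has no intra-node predecessor: upsampled + skip only
  expect_equal(conv_in(mt, "dec_h1_u1_conv1"), 32)
  mm <- build_model(network_config("tmdunet"))
  # dense skip adds chi_1^1 for unit 2
  expect_equal(conv_in(mm, "dec_h1_u2_conv1"), 64)
  expect_equal(conv_in(mm, "dec_h4_u3_conv1"), 128 * 2 + 128 + 3 * 128)
})

test_that("fusion head is three 1x1 read-outs plus a 1x1 fuse (55 parameters)", {
  m <- build_model(network_config("tunet"))
  fusion <- sum(sapply(c("subout1_conv", "subout2_conv", "subout3_conv",
                         "fusion_conv"), function(l)
    length(m$params[[l]]$W) + length(m$params[[l]]$b)))
  expect_identical(fusion, 55L)
})

test_that("forward pass yields four full-resolution probability maps", {
  m <- build_model(tiny_config("tmdunet"))
  p <- predict(m, rand_image(16, 1, seed = 5))
  expect_named(p, c("sub_output_1", "sub_output_2", "sub_output_3",
                    "final_output"))
  for (out in p) {
    expect_identical(dim(out), c(16L, 16L, 1L))
    expect_true(all(out > 0 & out < 1))
  }
  mu <- build_model(tiny_config("unet"))
  pu <- predict(mu, rand_image(16, 1, seed = 5))
  expect_named(pu, "final_output")
})

test_that("mismatched input shapes are rejected", {
  m <- build_model(tiny_config("tunet"))
  expect_error(predict(m, rand_image(32, 1)), "does not match")
})

test_that("parameter counts increase with output index and tmdunet dominates tunet", {
  mt <- build_model(network_config("tunet"))
  mm <- build_model(network_config("tmdunet"))
  ct <- sapply(1:3, function(i) count_parameters(mt, i)$parameters)
  cm <- sapply(1:3, function(i) count_parameters(mm, i)$parameters)
  expect_true(all(diff(ct) > 0))
  expect_true(all(diff(cm) > 0))
  expect_true(all(cm >= ct))
  expect_error(count_parameters(mt, 4), "output_index")
  expect_error(count_parameters(build_model(network_config("unet")), 2),
               "output_index")
})

test_that("reported totals equal an analytic count from recorded layer shapes", {
  for (variant in c("tunet", "tmdunet", "unet")) {
    m <- build_model(network_config(variant))
    analytic <- 0
    for (p in m$params) {
      if (!is.null(p$W)) {
        d <- dim(p$W)
        analytic <- analytic + prod(d) + if (is.null(p$b)) 0 else d[4]
      }
      if (!is.null(p$gamma)) analytic <- analytic + 2 * length(p$gamma)
    }
    n_out <- if (variant == "unet") 1L else 3L
    expect_identical(count_parameters(m, n_out)$parameters, analytic)
  }
})

test_that("a lone 1x1 single-filter conv on one channel has two parameters", {
  gb <- tmdunet:::new_graph_builder()
  x <- tmdunet:::gb_add(gb, "input", "input", out_shape = c(4, 4, 1))
  tmdunet:::gb_conv(gb, "c", x, 1L, k = 1L)
  p <- gb$params$c
  expect_identical(length(p$W) + length(p$b), 2L)
})

test_that("disabling MSI and dense skips reduces tmdunet to the tunet graph", {
  cfg_t <- network_config("tunet")
  cfg_r <- network_config("tmdunet", use_msi = FALSE, use_dense_skip = FALSE)
  sig_t <- graph_signature(build_model(cfg_t))
  sig_r <- graph_signature(build_model(cfg_r))
  expect_identical(sig_r, sig_t)
  # and the full tmdunet graph is NOT isomorphic to tunet
  expect_false(identical(graph_signature(build_model(network_config("tmdunet"))),
                         sig_t))
})

test_that("unit receptive fields are ordered by dilation rate", {
  rf <- unit_receptive_fields(network_config("tmdunet"))
  expect_identical(rf, c(13L, 9L, 5L))
  expect_gt(rf[1], rf[3])
})
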