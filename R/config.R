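#' Network configuration
#'
#' Declarative description of a model variant. The triple networks
#' (`"tunet"`, `"tmdunet"`) place three densely connected dilated-convolution
#' units at every resolution level (four encoder nodes, a transition node and
#' four decoder nodes), forming three parallel sub-networks read out by three
#' sub-outputs and a fused final output. `"tmdunet"` additionally consumes a
#' multi-scale pyramid of the input image and uses dense skip connections.
#' `"unet"` is the conventional 5-level baseline (two convolutions per level,
#' plain skip concatenation) kept for parameter-count comparison.
#'
#' @param variant one of `"unet"`, `"tunet"`, `"tmdunet"`.
#' @param input_size input height = width in pixels; must be divisible by 16
#'   (four pooling stages).
#' @param input_channels number of input channels. Defaults to 3 for the
#'   triple networks and 1 for the baseline, the configurations whose
#'   parameter totals match the published reference counts.
#' @param base_filters width of the first level. 16 for the triple networks,
#'   32 for the baseline.
#' @param node_filters integer vector of five per-level widths; default
#'   `base_filters * c(1, 2, 4, 8, 16)`.
#' @param dilation_rates dilation rate of each of the three units; unit i
#'   uses rate `4 - i` by default, so the first sub-network has the largest
#'   receptive field.
#' @param dropout_rate dropout probability applied after every convolution
#'   activation (training mode only).
#' @param use_msi include the multi-scale input pyramid (tmdunet only).
#' @param use_dense_skip decoder unit i receives encoder units 1..i instead
#'   of unit i alone (tmdunet only).
#'
#' @return an object of class `tmd_network_config`.
#' @export
network_config <- function(variant = c("tmdunet", "tunet", "unet"),
                           input_size = 128L,
                           input_channels = NULL,
                           base_filters = NULL,
                           node_filters = NULL,
                           dilation_rates = c(3L, 2L, 1L),
                           dropout_rate = 0.2,
                           use_msi = NULL,
                           use_dense_skip = NULL) {
  variant <- match.arg(variant)
  if (is.null(base_filters)) base_filters <- if (variant == "unet") 32L else 16L
  if (is.null(input_channels)) input_channels <- if (variant == "unet") 1L else 3L
  if (is.null(node_filters)) node_filters <- base_filters * c(1L, 2L, 4L, 8L, 16L)
  if (is.null(use_msi)) use_msi <- variant == "tmdunet"
  if (is.null(use_dense_skip)) use_dense_skip <- variant == "tmdunet"

  input_size <- as.integer(input_size)
  if (length(input_size) != 1L || input_size <= 0L || input_size %% 16L != 0L)
    stop("input_size must be a positive multiple of 16 (four pooling stages), got ",
         input_size)
  if (length(node_filters) != 5L || any(diff(node_filters) <= 0))
    stop("node_filters must be five strictly increasing widths")
  if (length(dilation_rates) != 3L || any(dilation_rates < 1L))
    stop("dilation_rates must give one positive rate per unit (three units)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (variant == "tunet" && (use_msi || use_dense_skip))
    stop("tunet has neither a multi-scale input pyramid nor dense skips")
  if (variant == "unet" && (use_msi || use_dense_skip))
    stop("the unet baseline has neither MSI nor dense skips")

  structure(list(variant = variant,
                 input_size = input_size,
                 input_channels = as.integer(input_channels),
                 base_filters = as.integer(base_filters),
                 node_filters = as.integer(node_filters),
                 units_per_node = 3L,
                 dilation_rates = as.integer(dilation_rates),
                 dropout_rate = dropout_rate,
                 use_msi = use_msi,
                 use_dense_skip = use_dense_skip),
            class = "tmd_network_config")
}

#' @export
print.tmd_network_config <- function(x, ...) {
  cat(sprintf("<%s config> %dx%dx%d, filters %s, dropout %.2f%s%s\n",
              x$variant, x$input_size, x$input_size, x$input_channels,
              paste(x$node_filters, collapse = "/"), x$dropout_rate,
              if (x$use_msi) ", MSI" else "",
              if (x$use_dense_skip) ", dense skips" else ""))
  invisible(x)
}

#' Single-unit receptive field of each convolution unit
#'
#' A unit is two 3x3 convolutions with dilation rate r; its receptive field
#' is `1 + 2 * r * (k - 1)` pixels. Unit 1 (rate 3 by default) therefore sees
#' a strictly wider neighbourhood than unit 3 (rate 1). Computed from
#' dilation bookkeeping, not empirically.
#'
#' @param config a [network_config()].
#' @return integer vector, receptive field in pixels per unit.
#' @export
unit_receptive_fields <- function(config) {
  stopifnot(inherits(config, "tmd_network_config"))
  1L + 2L * config$dilation_rates * 2L
}
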