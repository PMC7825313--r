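# Graph construction for the three model variants.
#
# Connectivity of the triple networks (one resolution level = one "node",
# three units per node, unit i uses dilation rate 4-i, every conv is
# followed by ReLU, batch normalization and dropout):
#
#   encoder node 1, unit i : [chi_1^1..chi_1^{i-1}, (I0 if MSI), image]
#   encoder node h>=2      : unit 1 and unit 3 receive the 2x2-max-pooled
#                            same-index map of node h-1 (plus the MSI level
#                            feature when enabled); unit 2 receives only the
#                            intra-node features.  This asymmetry is the
#                            connectivity that reproduces the published
#                            per-sub-network parameter counts exactly; see
#                            the methods vignette.
#   decoder node h, unit i : [gamma_h^1..gamma_h^{i-1}, tconv(gamma_{h+1}^i),
#                            skip], skip = chi_h^i or chi_h^1..i (dense)
#   fusion                 : 1x1 conv + sigmoid per sub-network, concat,
#                            1x1 conv + sigmoid -> final output
#
# MSI pyramid: the raw image is 2x2-max-pooled four times; each scale
# (including full resolution) passes through its own base_filters 3x3 conv +
# ReLU + BN.  The full-resolution feature is the stem output I0.
# Transposed convolutions are 2x2, stride 2, bias-free.

# one convolution unit: two (dilated conv -> relu -> bn -> dropout)
add_unit <- function(gb, prefix, input, filters, dilation, dropout) {
  x <- input
  for (j in 1:2) {
    x <- gb_conv(gb, paste0(prefix, "_conv", j), x, filters,
                 dilation = dilation)
    x <- gb_relu(gb, paste0(prefix, "_relu", j), x)
    x <- gb_bn(gb, paste0(prefix, "_bn", j), x)
    x <- gb_dropout(gb, paste0(prefix, "_drop", j), x, dropout)
  }
  x
}

concat_or_single <- function(gb, id, inputs) {
  if (length(inputs) == 1L) inputs[[1L]] else gb_concat(gb, id, inputs)
}

build_triple_graph <- function(config) {
  gb <- new_graph_builder()
  s <- config$input_size
  nf <- config$node_filters
  bf <- config$base_filters
  rates <- config$dilation_rates
  drop <- config$dropout_rate

  input <- gb_add(gb, "input", "input",
                  out_shape = c(s, s, config$input_channels))

  msi <- NULL
  if (config$use_msi) {
    # stem + per-scale convs on the max-pooled image pyramid
    msi <- character(5L)
    scaled <- input
    for (j in 0:4) {
      if (j > 0) scaled <- gb_maxpool(gb, paste0("msi_pool", j), scaled)
      nm <- if (j == 0) "stem" else paste0("msi_level", j)
      x <- gb_conv(gb, paste0(nm, "_conv"), scaled, bf)
      x <- gb_relu(gb, paste0(nm, "_relu"), x)
      msi[j + 1L] <- gb_bn(gb, paste0(nm, "_bn"), x)
    }
  }

  units <- matrix(NA_character_, 5L, 3L)   # chi_h^i node ids
  pooled <- matrix(NA_character_, 5L, 3L)  # M(chi_h^i)
  for (h in 1:5) {
    for (i in 1:3) {
      ins <- c(units[h, seq_len(i - 1L)])
      if (h == 1L) {
        if (config$use_msi) ins <- c(ins, msi[1L])
        ins <- c(ins, input)
      } else if (i != 2L) {
        ins <- c(ins, pooled[h - 1L, i])
        if (config$use_msi) ins <- c(ins, msi[h])
      }
      pre <- paste0("enc_h", h, "_u", i)
      x <- concat_or_single(gb, paste0(pre, "_in"), ins)
      units[h, i] <- add_unit(gb, pre, x, nf[h], rates[i], drop)
      if (h < 5L && i != 2L)
        pooled[h, i] <- gb_maxpool(gb, paste0(pre, "_pool"), units[h, i])
    }
  }

  below <- units[5L, ]                      # gamma_5 = transition outputs
  for (h in 4:1) {
    dec <- character(3L)
    for (i in 1:3) {
      pre <- paste0("dec_h", h, "_u", i)
      up <- gb_tconv(gb, paste0(pre, "_tconv"), below[i], nf[h])
      skips <- if (config$use_dense_skip) units[h, seq_len(i)] else units[h, i]
      ins <- c(dec[seq_len(i - 1L)], up, skips)
      x <- concat_or_single(gb, paste0(pre, "_in"), ins)
      dec[i] <- add_unit(gb, pre, x, nf[h], rates[i], drop)
    }
    below <- dec
  }

  subs <- character(3L)
  for (i in 1:3) {
    x <- gb_conv(gb, paste0("subout", i, "_conv"), below[i], 1L, k = 1L)
    subs[i] <- gb_sigmoid(gb, paste0("sub_output_", i), x)
  }
  x <- gb_concat(gb, "fusion_in", subs)
  x <- gb_conv(gb, "fusion_conv", x, 1L, k = 1L)
  final <- gb_sigmoid(gb, "final_output", x)

  list(gb = gb,
       outputs = c(sub_output_1 = subs[1], sub_output_2 = subs[2],
                   sub_output_3 = subs[3], final_output = final))
}

build_unet_graph <- function(config) {
  gb <- new_graph_builder()
  s <- config$input_size
  nf <- config$node_filters
  input <- gb_add(gb, "input", "input",
                  out_shape = c(s, s, config$input_channels))
  x <- input
  skips <- character(4L)
  for (h in 1:5) {
    for (j in 1:2) {
      x <- gb_conv(gb, paste0("enc", h, "_conv", j), x, nf[h])
      x <- gb_relu(gb, paste0("enc", h, "_relu", j), x)
      x <- gb_bn(gb, paste0("enc", h, "_bn", j), x)
      x <- gb_dropout(gb, paste0("enc", h, "_drop", j), x,
                      config$dropout_rate)
    }
    if (h < 5L) {
      skips[h] <- x
      x <- gb_maxpool(gb, paste0("enc", h, "_pool"), x)
    }
  }
  for (h in 4:1) {
    up <- gb_tconv(gb, paste0("dec", h, "_tconv"), x, nf[h])
    x <- gb_concat(gb, paste0("dec", h, "_in"), c(up, skips[h]))
    for (j in 1:2) {
      x <- gb_conv(gb, paste0("dec", h, "_conv", j), x, nf[h])
      x <- gb_relu(gb, paste0("dec", h, "_relu", j), x)
      x <- gb_bn(gb, paste0("dec", h, "_bn", j), x)
      x <- gb_dropout(gb, paste0("dec", h, "_drop", j), x,
                      config$dropout_rate)
    }
  }
  x <- gb_conv(gb, "out_conv", x, 1L, k = 1L)
  final <- gb_sigmoid(gb, "final_output", x)
  list(gb = gb, outputs = c(final_output = final))
}

#' Build a segmentation model
#'
#' Assembles the computation graph of the configured variant and initializes
#' all weights (he-normal for convolutions, unit scale / zero shift for
#' batch normalization). The triple networks expose four named outputs
#' (`sub_output_1..3` and `final_output`); the baseline exposes
#' `final_output` only.
#'
#' @param config a [network_config()].
#' @return an object of class `tmd_model`.
#' @examples
#' m <- build_model(network_config("tunet", input_size = 16, base_filters = 2,
#'                                 node_filters = c(2, 4, 8, 16, 32)))
#' m
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "tmd_network_config"))
  g <- if (config$variant == "unet") build_unet_graph(config)
       else build_triple_graph(config)
  structure(list(config = config,
                 nodes = g$gb$nodes,
                 params = g$gb$params,
                 outputs = g$outputs),
            class = "tmd_model")
}

#' @export
print.tmd_model <- function(x, ...) {
  rep_ <- parameter_report(x)
  cat(sprintf("<tmd_model: %s> %d graph nodes, %d outputs\n",
              x$config$variant, length(x$nodes), length(x$outputs)))
  print(rep_, row.names = FALSE)
  invisible(x)
}

# ids of all graph ancestors of `id` (inclusive)
graph_ancestors <- function(model, id) {
  seen <- new.env(parent = emptyenv())
  stack <- id
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (!is.null(seen[[cur]])) next
    seen[[cur]] <- TRUE
    stack <- c(stack, model$nodes[[cur]]$inputs)
  }
  ls(seen)
}

n_trainable <- function(params, layers) {
  tot <- 0
  for (layer in layers) {
    p <- params[[layer]]
    for (nm in intersect(names(p), TRAINABLE)) tot <- tot + length(p[[nm]])
  }
  tot
}

#' Count trainable parameters upstream of one sub-network output
#'
#' For the triple networks, output index i reads the subgraph feeding
#' `sub_output_i` (units 1..i of every node, their transposed convolutions,
#' the shared input path, and the 1x1 read-out convolution); index 3 is the
#' complete model including the fusion head. For the baseline only index 1
#' is defined.
#'
#' @param model a [build_model()] result.
#' @param output_index 1, 2 or 3 (1 for the baseline).
#' @return named list with `parameters` (integer) and `millions`
#'   (parameters / 1e6 rounded to 3 decimals).
#' @export
count_parameters <- function(model, output_index = NULL) {
  stopifnot(inherits(model, "tmd_model"))
  n_out <- if (model$config$variant == "unet") 1L else 3L
  if (is.null(output_index)) output_index <- n_out
  if (!output_index %in% seq_len(n_out))
    stop("output_index must be in 1..", n_out, " for variant ",
         model$config$variant)
  target <- if (model$config$variant == "unet") model$outputs[["final_output"]]
            else if (output_index == 3L) model$outputs[["final_output"]]
            else model$outputs[[paste0("sub_output_", output_index)]]
  anc <- graph_ancestors(model, target)
  layers <- unique(stats::na.omit(
    vapply(model$nodes[anc], function(nd) nd$layer, character(1))))
  n <- n_trainable(model$params, layers)
  list(parameters = n, millions = round(n / 1e6, 3))
}

#' Per-output trainable-parameter report
#'
#' @param model a [build_model()] result.
#' @return data frame with columns `variant`, `output_index`,
#'   `parameter_count`, `millions_3dp`. Counts are strictly increasing in the
#'   output index because each sub-network's subgraph contains the previous
#'   one's.
#' @export
parameter_report <- function(model) {
  stopifnot(inherits(model, "tmd_model"))
  n_out <- if (model$config$variant == "unet") 1L else 3L
  rows <- lapply(seq_len(n_out), function(i) {
    ct <- count_parameters(model, i)
    data.frame(variant = model$config$variant, output_index = i,
               parameter_count = ct$parameters, millions_3dp = ct$millions)
  })
  do.call(rbind, rows)
}

#' Canonical structural signature of a model graph
#'
#' One string per graph node: operation, arguments, output shape, parameter
#' shapes and the positions of its inputs in build order. Two models with
#' identical signatures are structurally identical (same layer shapes wired
#' the same way), regardless of node naming or weight values.
#'
#' @param model a [build_model()] result.
#' @return character vector, one entry per graph node.
#' @export
graph_signature <- function(model) {
  pos <- stats::setNames(seq_along(model$nodes), names(model$nodes))
  vapply(model$nodes, function(nd) {
    pshape <- if (!is.na(nd$layer)) {
      p <- model$params[[nd$layer]]
      paste(vapply(intersect(names(p), TRAINABLE), function(nm)
        paste0(nm, ":", paste(dim(p[[nm]]) %||% length(p[[nm]]),
                              collapse = "x")), character(1)),
        collapse = ",")
    } else ""
    paste(nd$op,
          paste(unlist(nd$args), collapse = ","),
          paste(nd$out_shape, collapse = "x"),
          pshape,
          paste(pos[nd$inputs], collapse = ","),
          sep = "|")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a model on one image
#'
#' @param object a `tmd_model`.
#' @param image numeric array `H x W x C` (a matrix is treated as one
#'   channel) matching the configured input size.
#' @param ... unused.
#' @return named list of output arrays (`H x W x 1`, values in (0,1)):
#'   `sub_output_1..3` and `final_output` for the triple networks,
#'   `final_output` for the baseline.
#' @export
predict.tmd_model <- function(object, image, ...) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  fw <- graph_forward(object, image, training = FALSE, keep_cache = FALSE)
  lapply(object$outputs, function(id) fw$vals[[id]])
}
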