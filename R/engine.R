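#' @useDynLib tmdunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A small static-graph engine.
#
# A model is a list:
#   nodes   list of graph nodes in topological order; each node is
#           list(id, op, inputs, layer, args, out_shape)
#   params  named list: params[[layer]] is a named list of numeric arrays;
#           entries named W, b, gamma, beta are trainable, everything else
#           (running BN moments) is state.
#   outputs named character vector mapping output names to node ids
#
# Forward walks nodes in order; backward walks them in reverse, accumulating
# gradients per node id and per parameter.  Tensors are arrays dim c(H,W,C).
# ---------------------------------------------------------------------------

TRAINABLE <- c("W", "b", "gamma", "beta")

new_graph_builder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$params <- list()
  gb
}

gb_add <- function(gb, id, op, inputs = character(), layer = NA_character_,
                   args = list(), out_shape) {
  if (id %in% names(gb$nodes)) stop("duplicate graph node id: ", id)
  gb$nodes[[id]] <- list(id = id, op = op, inputs = inputs, layer = layer,
                         args = args, out_shape = out_shape)
  id
}

node_shape <- function(gb, id) gb$nodes[[id]]$out_shape

#' @keywords internal
he_normal <- function(shape, fan_in) {
  array(stats::rnorm(prod(shape), sd = sqrt(2 / fan_in)), dim = shape)
}

# Register a 2-D convolution (size-preserving, dilated) and return node id.
gb_conv <- function(gb, id, input, filters, k = 3L, dilation = 1L,
                    bias = TRUE) {
  sh <- node_shape(gb, input)
  cin <- sh[3]
  layer <- id
  gb$params[[layer]] <- c(
    list(W = he_normal(c(k, k, cin, filters), k * k * cin)),
    if (bias) list(b = numeric(filters)))
  gb_add(gb, id, "conv", input, layer,
         args = list(k = k, dilation = as.integer(dilation), bias = bias),
         out_shape = c(sh[1], sh[2], filters))
}

gb_tconv <- function(gb, id, input, filters) {
  sh <- node_shape(gb, input)
  gb$params[[id]] <- list(W = he_normal(c(2, 2, sh[3], filters), 4 * sh[3]))
  gb_add(gb, id, "tconv", input, id, args = list(),
         out_shape = c(sh[1] * 2, sh[2] * 2, filters))
}

gb_bn <- function(gb, id, input, eps = 1e-3, momentum = 0.9) {
  sh <- node_shape(gb, input)
  c_ <- sh[3]
  gb$params[[id]] <- list(gamma = rep(1, c_), beta = numeric(c_),
                          rmean = numeric(c_), rvar = rep(1, c_))
  gb_add(gb, id, "bn", input, id,
         args = list(eps = eps, momentum = momentum), out_shape = sh)
}

gb_relu <- function(gb, id, input)
  gb_add(gb, id, "relu", input, out_shape = node_shape(gb, input))

gb_sigmoid <- function(gb, id, input)
  gb_add(gb, id, "sigmoid", input, out_shape = node_shape(gb, input))

gb_dropout <- function(gb, id, input, rate)
  gb_add(gb, id, "dropout", input, args = list(rate = rate),
         out_shape = node_shape(gb, input))

gb_maxpool <- function(gb, id, input) {
  sh <- node_shape(gb, input)
  if (sh[1] %% 2L != 0L || sh[2] %% 2L != 0L)
    stop("max-pooling an odd-sized map: ", paste(sh, collapse = "x"))
  gb_add(gb, id, "maxpool", input, out_shape = c(sh[1] / 2, sh[2] / 2, sh[3]))
}

gb_concat <- function(gb, id, inputs) {
  shs <- lapply(inputs, node_shape, gb = gb)
  hw <- unique(vapply(shs, function(s) paste(s[1], s[2]), character(1)))
  if (length(hw) != 1L)
    stop("concat of maps with mismatched spatial sizes: ",
         paste(vapply(shs, function(s) paste(s, collapse = "x"),
                      character(1)), collapse = ", "))
  gb_add(gb, id, "concat", inputs,
         out_shape = c(shs[[1]][1], shs[[1]][2],
                       sum(vapply(shs, function(s) s[3], numeric(1)))))
}

# -- forward ----------------------------------------------------------------

#' @keywords internal
graph_forward <- function(model, x, training = FALSE, keep_cache = training) {
  vals <- new.env(parent = emptyenv())
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  bn_updates <- list()
  for (nd in model$nodes) {
    v <- switch(nd$op,
      input = {
        if (!identical(dim(x), as.integer(nd$out_shape)) &&
            !identical(dim(x), nd$out_shape))
          stop("input shape ", paste(dim(x), collapse = "x"),
               " does not match model input ",
               paste(nd$out_shape, collapse = "x"))
        x
      },
      conv = {
        p <- model$params[[nd$layer]]
        cpp_conv2d_fwd(vals[[nd$inputs]], p$W,
                       if (is.null(p$b)) numeric(0) else p$b,
                       nd$args$dilation)
      },
      tconv = cpp_tconv2_fwd(vals[[nd$inputs]], model$params[[nd$layer]]$W),
      bn = {
        xin <- vals[[nd$inputs]]
        p <- model$params[[nd$layer]]
        d <- dim(xin)
        xm <- matrix(xin, d[1] * d[2], d[3])
        if (training) {
          mu <- colMeans(xm)
          va <- colMeans(xm^2) - mu^2
          mom <- nd$args$momentum
          bn_updates[[nd$layer]] <- list(
            rmean = mom * p$rmean + (1 - mom) * mu,
            rvar = mom * p$rvar + (1 - mom) * va)
        } else {
          mu <- p$rmean; va <- p$rvar
        }
        inv <- 1 / sqrt(va + nd$args$eps)
        xhat <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
        y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
        if (keep_cache) cache[[nd$id]] <- list(xhat = xhat, inv = inv)
        array(y, dim = d)
      },
      relu = pmax(vals[[nd$inputs]], 0),
      sigmoid = 1 / (1 + exp(-vals[[nd$inputs]])),
      dropout = {
        xin <- vals[[nd$inputs]]
        if (training && nd$args$rate > 0) {
          keep <- (stats::runif(length(xin)) >= nd$args$rate) /
            (1 - nd$args$rate)
          if (keep_cache) cache[[nd$id]] <- keep
          xin * keep
        } else xin
      },
      maxpool = {
        r <- cpp_maxpool2_fwd(vals[[nd$inputs]])
        if (keep_cache) cache[[nd$id]] <- r$idx
        r$out
      },
      concat = {
        parts <- lapply(nd$inputs, function(i) vals[[i]])
        array(unlist(parts, use.names = FALSE), dim = nd$out_shape)
      },
      stop("unknown op: ", nd$op))
    dim(v) <- nd$out_shape
    vals[[nd$id]] <- v
  }
  list(vals = vals, cache = cache, bn_updates = bn_updates)
}

# -- backward ---------------------------------------------------------------

# out_grads: named list mapping node ids to gradient arrays.
# Returns list(param_grads = <layer -> param -> array>).
#' @keywords internal
graph_backward <- function(model, fw, out_grads) {
  grads <- new.env(parent = emptyenv())
  for (id in names(out_grads)) grads[[id]] <- out_grads[[id]]
  pg <- new.env(parent = emptyenv())
  add_grad <- function(id, g) {
    cur <- grads[[id]]
    grads[[id]] <- if (is.null(cur)) g else cur + g
  }
  add_pgrad <- function(layer, name, g) {
    cur <- pg[[layer]]
    if (is.null(cur)) cur <- list()
    cur[[name]] <- if (is.null(cur[[name]])) g else cur[[name]] + g
    pg[[layer]] <- cur
  }
  vals <- fw$vals; cache <- fw$cache
  for (nd in rev(model$nodes)) {
    g <- grads[[nd$id]]
    if (is.null(g) || nd$op == "input") next
    dim(g) <- nd$out_shape
    switch(nd$op,
      conv = {
        p <- model$params[[nd$layer]]
        r <- cpp_conv2d_bwd(vals[[nd$inputs]], p$W, g, nd$args$dilation,
                            nd$args$bias)
        add_pgrad(nd$layer, "W", r$gW)
        if (nd$args$bias) add_pgrad(nd$layer, "b", r$gb)
        add_grad(nd$inputs, r$gx)
      },
      tconv = {
        r <- cpp_tconv2_bwd(vals[[nd$inputs]], model$params[[nd$layer]]$W, g)
        add_pgrad(nd$layer, "W", r$gW)
        add_grad(nd$inputs, r$gx)
      },
      bn = {
        p <- model$params[[nd$layer]]
        cc <- cache[[nd$id]]
        d <- nd$out_shape; n <- d[1] * d[2]
        gm <- matrix(g, n, d[3])
        add_pgrad(nd$layer, "gamma", colSums(gm * cc$xhat))
        add_pgrad(nd$layer, "beta", colSums(gm))
        gxhat <- sweep(gm, 2, p$gamma, "*")
        # d/dx of per-sample normalization
        t1 <- sweep(gxhat, 2, colMeans(gxhat), "-")
        t2 <- sweep(cc$xhat, 2, colMeans(gxhat * cc$xhat), "*")
        gx <- sweep(t1 - t2, 2, cc$inv, "*")
        add_grad(nd$inputs, array(gx, dim = d))
      },
      relu = add_grad(nd$inputs, g * (vals[[nd$id]] > 0)),
      sigmoid = {
        y <- vals[[nd$id]]
        add_grad(nd$inputs, g * y * (1 - y))
      },
      dropout = {
        keep <- cache[[nd$id]]
        add_grad(nd$inputs, if (is.null(keep)) g else g * keep)
      },
      maxpool = add_grad(nd$inputs,
                         cpp_maxpool2_bwd(g, cache[[nd$id]],
                                          as.integer(
                                            node_shape(model, nd$inputs)))),
      concat = {
        off <- 0L
        for (i in nd$inputs) {
          ci <- node_shape(model, i)[3]
          add_grad(i, g[, , off + seq_len(ci), drop = FALSE])
          off <- off + ci
        }
      })
  }
  as.list(pg)
}

# -- Adam -------------------------------------------------------------------

#' @keywords internal
adam_state <- function(params) {
  st <- list(t = 0)
  for (layer in names(params))
    for (nm in intersect(names(params[[layer]]), TRAINABLE)) {
      z <- params[[layer]][[nm]] * 0
      st$m[[layer]][[nm]] <- z
      st$v[[layer]][[nm]] <- z
    }
  st
}

#' @keywords internal
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (layer in names(grads)) {
    for (nm in names(grads[[layer]])) {
      g <- grads[[layer]][[nm]]
      m <- beta1 * state$m[[layer]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v[[layer]][[nm]] + (1 - beta2) * g * g
      state$m[[layer]][[nm]] <- m
      state$v[[layer]][[nm]] <- v
      params[[layer]][[nm]] <- params[[layer]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
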