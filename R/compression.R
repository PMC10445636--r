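# Model compression: one-input embedding networks are replaced by
# per-interval quintic polynomials whose six coefficients reproduce the
# network's value, first and second derivative at both interval endpoints;
# the tabulated evaluation is then merged with the environment-matrix
# contraction, skipping padded neighbor slots entirely.

#' Tabulate a one-input network as piecewise quintics
#'
#' The domain is divided into `lc` even intervals; on each, the polynomial
#' `a t^5 + b t^4 + c t^3 + d t^2 + e t + f` in `t = x - x_l` is fitted from
#' the network's value and first two derivatives at the interval endpoints
#' (computed by exact propagation through the layers), so the table is a
#' two-point quintic Hermite interpolant: C2 across nodes and exact at
#' them.
#'
#' @param net a one-input network with a twice-differentiable activation.
#' @param domain numeric `c(lo, hi)` input range.
#' @param lc number of intervals.
#' @return a `dp_tabulated_net` (grid plus `lc x 6 x M` coefficients).
#' @export
tabulate_network <- function(net, domain, lc) {
  stopifnot(length(domain) == 2L, domain[1L] < domain[2L], lc >= 1L)
  if (net$n_in != 1L)
    stop("only one-input networks can be tabulated", call. = FALSE)
  for (layer in net$layers)
    if (!act_is_smooth(layer$activation))
      stop("cannot compress a network with activation '", layer$activation,
           "': first derivative is discontinuous", call. = FALSE)
  xs <- seq(domain[1L], domain[2L], length.out = lc + 1L)
  ev <- net_eval_d2(net, xs)
  m <- ncol(ev$y)
  dx <- xs[2L] - xs[1L]
  co <- array(0, dim = c(lc, 6L, m))
  y0 <- ev$y[-(lc + 1L), , drop = FALSE];  y1 <- ev$y[-1L, , drop = FALSE]
  p0 <- ev$d1[-(lc + 1L), , drop = FALSE]; p1 <- ev$d1[-1L, , drop = FALSE]
  q0 <- ev$d2[-(lc + 1L), , drop = FALSE]; q1 <- ev$d2[-1L, , drop = FALSE]
  hh <- y1 - y0
  co[, 1L, ] <- (12 * hh - 6 * (p1 + p0) * dx + (q1 - q0) * dx^2) /
    (2 * dx^5)
  co[, 2L, ] <- (-30 * hh + (14 * p1 + 16 * p0) * dx +
                   (-2 * q1 + 3 * q0) * dx^2) / (2 * dx^4)
  co[, 3L, ] <- (20 * hh - (8 * p1 + 12 * p0) * dx +
                   (q1 - 3 * q0) * dx^2) / (2 * dx^3)
  co[, 4L, ] <- q0 / 2
  co[, 5L, ] <- p0
  co[, 6L, ] <- y0
  structure(list(lo = xs[1L], hi = xs[lc + 1L], dx = dx, lc = as.integer(lc),
                 coeffs = co, m = m),
            class = "dp_tabulated_net")
}

#' @export
print.dp_tabulated_net <- function(x, ...) {
  cat("Tabulated network:", x$lc, "intervals on [",
      format(x$lo), ",", format(x$hi), "],", x$m, "outputs\n")
  if (!is.null(x$ext_hi)) cat("  with coarse extension to",
                              format(x$ext_hi$hi), "\n")
  invisible(x)
}

# locate interval by floor division; the last interval is closed at hi
tab_interval <- function(tab, x) {
  l <- pmin(pmax(floor((x - tab$lo) / tab$dx) + 1, 1), tab$lc)
  as.integer(l)
}

#' Evaluate a tabulated network
#'
#' @param tab a [tabulate_network()] result.
#' @param x numeric vector of scalar inputs; must lie within the grid (or
#'   its coarse extension, when present).
#' @param deriv 0, 1 or 2.
#' @return `length(x) x M` matrix.
#' @export
tab_eval <- function(tab, x, deriv = 0L) {
  inmain <- x >= tab$lo - 1e-12 & x <= tab$hi + 1e-12
  if (!all(inmain)) {
    out <- matrix(0, length(x), tab$m)
    ext_ok <- rep(FALSE, length(x))
    for (seg in c("ext_lo", "ext_hi")) {
      e <- tab[[seg]]
      if (is.null(e)) next
      inseg <- !inmain & x >= e$lo - 1e-12 & x <= e$hi + 1e-12
      if (any(inseg)) {
        out[inseg, ] <- tab_eval_core(e, x[inseg], deriv)
        ext_ok <- ext_ok | inseg
      }
    }
    if (!all(inmain | ext_ok))
      stop("tabulated evaluation outside the grid: x = ",
           format(x[which(!(inmain | ext_ok))[1L]]), " not in [",
           format(tab$lo), ", ", format(tab$hi), "]", call. = FALSE)
    out[inmain, ] <- tab_eval_core(tab, x[inmain], deriv)
    return(out)
  }
  tab_eval_core(tab, x, deriv)
}

tab_eval_core <- function(tab, x, deriv = 0L) {
  l <- tab_interval(tab, x)
  t <- x - (tab$lo + (l - 1) * tab$dx)
  co <- tab$coeffs
  out <- matrix(0, length(x), tab$m)
  for (k in seq_len(tab$m)) {
    a <- co[l, 1L, k]; b <- co[l, 2L, k]; cc <- co[l, 3L, k]
    d <- co[l, 4L, k]; e <- co[l, 5L, k]; f <- co[l, 6L, k]
    out[, k] <- switch(as.character(deriv),
      "0" = ((((a * t + b) * t + cc) * t + d) * t + e) * t + f,
      "1" = (((5 * a * t + 4 * b) * t + 3 * cc) * t + 2 * d) * t + e,
      "2" = ((20 * a * t + 12 * b) * t + 6 * cc) * t + 2 * d,
      stop("deriv must be 0, 1 or 2", call. = FALSE))
  }
  out
}

#' Merged tabulated contraction
#'
#' Computes `G^T R` with `G` rows produced by the tabulated network, using
#' only the real (non-padded) neighbor rows — the padded slots are skipped
#' by precise neighbor indexing, which cannot change the result because
#' their environment-matrix rows are exactly zero.
#'
#' @param tab a tabulated network.
#' @param s switching values of the real neighbors of one atom.
#' @param R environment-matrix rows (`n_real x 4`) of the same neighbors.
#' @return `M x 4` matrix `G^T R`.
#' @export
merged_contraction <- function(tab, s, R) {
  R <- as.matrix(R)
  if (length(s) == 0L) return(matrix(0, tab$m, ncol(R)))
  out <- matrix(0, tab$m, ncol(R))
  G <- tab_eval(tab, s)
  # one column of G^T at a time, deposited as an outer product
  for (j in seq_along(s))
    out <- out + tcrossprod(G[j, ], R[j, ])
  out
}

# observed embedding-input range (s, or theta for the three-body case) of a
# model over a dataset, per routing group
observed_input_range <- function(model, data) {
  cfg <- model$descriptor
  lo <- Inf; hi <- -Inf
  for (fr in data$frames) {
    nl <- build_neighbor_list(fr$frame, cfg$rcut, desc_sel(cfg, model$nt))
    if (length(nl$i) == 0L) next
    s <- switch_fn(nl$dist, cfg$rcut_smth, cfg$rcut)
    if (cfg$kind == "se_e3") {
      rhat <- nl$rvec / nl$dist
      R4 <- cbind(s, s * rhat)
      for (a in seq_len(fr$frame$n_atoms)) {
        rows <- nl_rows(nl, a)
        if (length(rows) == 0L) next
        th <- tcrossprod(R4[rows, , drop = FALSE])
        lo <- min(lo, th); hi <- max(hi, th)
      }
    } else {
      lo <- min(lo, s, 0); hi <- max(hi, s)
    }
  }
  if (!is.finite(lo)) stop("no pairs observed in the data", call. = FALSE)
  c(lo, hi)
}

#' Compress an energy model
#'
#' Replaces every one-input embedding network of a trained two- or
#' three-body embedding descriptor by its piecewise-quintic table over the
#' input range observed in the training data, plus a coarser extension
#' table widening the domain by `extrapolation_factor` for configurations
#' outside the training range.  Attention and local-frame descriptors are
#' not compressible.
#'
#' @param model a trained `dp_energy_model` with descriptor kind `se_e2_a`,
#'   `se_e2_r` or `se_e3` and per-pair or per-neighbor routing.
#' @param data the training `dp_system`, used for the observed input range.
#' @param lc number of table intervals.
#' @param extrapolation_factor domain widening of the coarse extension.
#' @return the compressed model.
#' @export
compress_model <- function(model, data, lc = 1024L,
                           extrapolation_factor = 5) {
  cfg <- model$descriptor
  if (!cfg$kind %in% c("se_e2_a", "se_e2_r", "se_e3"))
    stop("compression supports se_e2_a, se_e2_r and se_e3 descriptors only",
         call. = FALSE)
  if (cfg$routing == "type_embed")
    stop("type-embedding routed networks take multi-dimensional input and ",
         "cannot be tabulated", call. = FALSE)
  rng <- observed_input_range(model, data)
  span <- rng[2L] - rng[1L]
  make_tab <- function(net) {
    tab <- tabulate_network(net, rng, lc)
    ext <- span * (extrapolation_factor - 1)
    lc_ext <- max(16L, ceiling(lc / 8))
    if (ext > 0) {
      tab$ext_hi <- tabulate_network(net, c(rng[2L], rng[2L] + ext), lc_ext)
      if (cfg$kind == "se_e3")
        tab$ext_lo <- tabulate_network(net, c(rng[1L] - ext, rng[1L]),
                                       lc_ext)
    }
    tab
  }
  dp <- model$params$desc
  dp$tab <- if (cfg$routing == "pair")
    lapply(dp$emb, function(row) lapply(row, make_tab))
  else lapply(dp$emb, make_tab)
  model$params$desc <- dp
  model$compressed <- TRUE
  model$tab_range <- rng
  model
}
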