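# Reverse-mode automatic differentiation on a dynamic tape of matrix
# operations.  Values are evaluated eagerly; every node stores its numeric
# value (a base matrix), its parent ids and the name of the primitive that
# produced it.  Gradients are obtained by a single reverse sweep
# (ad_backward); Jacobian-vector products are obtained by replaying the tape
# forward and expressing each tangent with tape primitives (ad_jvp), so that
# a subsequent reverse sweep over the extended tape yields exact second-order
# quantities such as d/dtheta of force components.
#
# The primitive set is deliberately small; anything else (layer norm,
# softmin, switching envelopes) is composed from it.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$needs <- logical(512L)
  t$n <- 0L
  t
}

ad_node <- function(tape, op, value, parents = integer(0), extra = NULL,
                    needs = NULL) {
  # value/parents promises may hold nested op calls that append to the
  # tape; force them before the new id is taken from the counter
  force(value)
  force(parents)
  if (is.null(needs)) needs <- any(tape$needs[parents])
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$needs <- c(tape$needs, logical(length(tape$needs)))
  }
  tape$nodes[[n]] <- list(op = op, value = value, parents = parents,
                          extra = extra, needs = needs)
  tape$needs[n] <- needs
  tape$n <- n
  n
}

ad_value <- function(tape, id) {
  # force id before touching tape$nodes: a nested op call in the id
  # argument appends to the tape, and the node list must be read after
  force(id)
  tape$nodes[[id]]$value
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Leaves -----------------------------------------------------------------

ad_input <- function(tape, value) ad_node(tape, "leaf", as_mat(value), needs = TRUE)
ad_const <- function(tape, value) ad_node(tape, "leaf", as_mat(value), needs = FALSE)

# Primitive registry ------------------------------------------------------
# bwd(node, grad, tape, need): list of parent cotangents (NULL where unneeded)
# tan(tape, id, node, tan_ids): node id of the output tangent; tan_ids[p] == 0
#   marks a structurally zero tangent.

AD_OPS <- new.env(parent = emptyenv())

ad_defop <- function(name, bwd, tan = NULL) {
  assign(name, list(bwd = bwd, tan = tan), envir = AD_OPS)
  invisible(name)
}

# helper used by tangent rules: add two optional (possibly 0) tangent ids
tan_add <- function(tape, a, b) {
  if (a == 0L) return(b)
  if (b == 0L) return(a)
  ad_add(tape, a, b)
}

# -- arithmetic -----------------------------------------------------------

ad_add <- function(tape, a, b)
  ad_node(tape, "add", ad_value(tape, a) + ad_value(tape, b), c(a, b))
ad_defop("add",
  bwd = function(nd, g, tape, need) list(g, g),
  tan = function(tape, id, nd, tn)
    tan_add(tape, tn[nd$parents[1L]], tn[nd$parents[2L]]))

ad_sub <- function(tape, a, b)
  ad_node(tape, "sub", ad_value(tape, a) - ad_value(tape, b), c(a, b))
ad_defop("sub",
  bwd = function(nd, g, tape, need) list(g, -g),
  tan = function(tape, id, nd, tn) {
    ta <- tn[nd$parents[1L]]; tb <- tn[nd$parents[2L]]
    if (tb == 0L) return(ta)
    if (ta == 0L) return(ad_neg(tape, tb))
    ad_sub(tape, ta, tb)
  })

ad_neg <- function(tape, a) ad_node(tape, "neg", -ad_value(tape, a), a)
ad_defop("neg",
  bwd = function(nd, g, tape, need) list(-g),
  tan = function(tape, id, nd, tn) ad_neg(tape, tn[nd$parents[1L]]))

ad_mul <- function(tape, a, b)
  ad_node(tape, "mul", ad_value(tape, a) * ad_value(tape, b), c(a, b))
ad_defop("mul",
  bwd = function(nd, g, tape, need) {
    va <- ad_value(tape, nd$parents[1L]); vb <- ad_value(tape, nd$parents[2L])
    list(if (need[1L]) g * vb else NULL, if (need[2L]) g * va else NULL)
  },
  tan = function(tape, id, nd, tn) {
    a <- nd$parents[1L]; b <- nd$parents[2L]
    t1 <- if (tn[a] != 0L) ad_mul(tape, tn[a], b) else 0L
    t2 <- if (tn[b] != 0L) ad_mul(tape, a, tn[b]) else 0L
    tan_add(tape, t1, t2)
  })

ad_smul <- function(tape, a, c)
  ad_node(tape, "smul", ad_value(tape, a) * c, a, extra = c)
ad_defop("smul",
  bwd = function(nd, g, tape, need) list(g * nd$extra),
  tan = function(tape, id, nd, tn) ad_smul(tape, tn[nd$parents[1L]], nd$extra))

ad_matmul <- function(tape, a, b)
  ad_node(tape, "matmul", ad_value(tape, a) %*% ad_value(tape, b), c(a, b))
ad_defop("matmul",
  bwd = function(nd, g, tape, need) {
    va <- ad_value(tape, nd$parents[1L]); vb <- ad_value(tape, nd$parents[2L])
    list(if (need[1L]) tcrossprod(g, vb) else NULL,
         if (need[2L]) crossprod(va, g) else NULL)
  },
  tan = function(tape, id, nd, tn) {
    a <- nd$parents[1L]; b <- nd$parents[2L]
    t1 <- if (tn[a] != 0L) ad_matmul(tape, tn[a], b) else 0L
    t2 <- if (tn[b] != 0L) ad_matmul(tape, a, tn[b]) else 0L
    tan_add(tape, t1, t2)
  })

ad_transpose <- function(tape, a)
  ad_node(tape, "transpose", t(ad_value(tape, a)), a)
ad_defop("transpose",
  bwd = function(nd, g, tape, need) list(t(g)),
  tan = function(tape, id, nd, tn) ad_transpose(tape, tn[nd$parents[1L]]))

# -- reductions and shape -------------------------------------------------

ad_rowsums <- function(tape, a)
  ad_node(tape, "rowsums", matrix(.rowSums(ad_value(tape, a),
    nrow(ad_value(tape, a)), ncol(ad_value(tape, a))), ncol = 1L), a)
ad_defop("rowsums",
  bwd = function(nd, g, tape, need) {
    v <- ad_value(tape, nd$parents[1L])
    list(matrix(g, nrow(v), ncol(v)))
  },
  tan = function(tape, id, nd, tn) ad_rowsums(tape, tn[nd$parents[1L]]))

ad_colsums <- function(tape, a)
  ad_node(tape, "colsums", matrix(.colSums(ad_value(tape, a),
    nrow(ad_value(tape, a)), ncol(ad_value(tape, a))), nrow = 1L), a)
ad_defop("colsums",
  bwd = function(nd, g, tape, need) {
    v <- ad_value(tape, nd$parents[1L])
    list(matrix(g, nrow(v), ncol(v), byrow = TRUE))
  },
  tan = function(tape, id, nd, tn) ad_colsums(tape, tn[nd$parents[1L]]))

ad_sumall <- function(tape, a)
  ad_node(tape, "sumall", matrix(sum(ad_value(tape, a)), 1L, 1L), a)
ad_defop("sumall",
  bwd = function(nd, g, tape, need) {
    v <- ad_value(tape, nd$parents[1L])
    list(matrix(g[1L], nrow(v), ncol(v)))
  },
  tan = function(tape, id, nd, tn) ad_sumall(tape, tn[nd$parents[1L]]))

ad_slice_rows <- function(tape, a, idx)
  ad_node(tape, "slice_rows", ad_value(tape, a)[idx, , drop = FALSE], a,
          extra = idx)
ad_defop("slice_rows",
  bwd = function(nd, g, tape, need) {
    v <- ad_value(tape, nd$parents[1L])
    z <- matrix(0, nrow(v), ncol(v))
    rs <- rowsum(g, nd$extra)
    z[as.integer(rownames(rs)), ] <- rs
    list(z)
  },
  tan = function(tape, id, nd, tn)
    ad_slice_rows(tape, tn[nd$parents[1L]], nd$extra))

ad_slice_cols <- function(tape, a, idx)
  ad_node(tape, "slice_cols", ad_value(tape, a)[, idx, drop = FALSE], a,
          extra = idx)
ad_defop("slice_cols",
  bwd = function(nd, g, tape, need) {
    v <- ad_value(tape, nd$parents[1L])
    z <- matrix(0, nrow(v), ncol(v))
    z[, nd$extra] <- z[, nd$extra] + g
    list(z)
  },
  tan = function(tape, id, nd, tn)
    ad_slice_cols(tape, tn[nd$parents[1L]], nd$extra))

# scatter rows of a into an n-row zero matrix at positions idx
ad_scatter_rows <- function(tape, a, idx, n) {
  v <- ad_value(tape, a)
  z <- matrix(0, n, ncol(v))
  z[idx, ] <- v
  ad_node(tape, "scatter_rows", z, a, extra = list(idx = idx, n = n))
}
ad_defop("scatter_rows",
  bwd = function(nd, g, tape, need) list(g[nd$extra$idx, , drop = FALSE]),
  tan = function(tape, id, nd, tn)
    ad_scatter_rows(tape, tn[nd$parents[1L]], nd$extra$idx, nd$extra$n))

# per-group row sums: rows of a accumulated by integer group in 1..ngroup
ad_rowsum_groups <- function(tape, a, groups, ngroup) {
  v <- ad_value(tape, a)
  z <- matrix(0, ngroup, ncol(v))
  rs <- rowsum(v, groups)
  z[as.integer(rownames(rs)), ] <- rs
  ad_node(tape, "rowsum_groups", z, a, extra = list(g = groups, n = ngroup))
}
ad_defop("rowsum_groups",
  bwd = function(nd, g, tape, need) list(g[nd$extra$g, , drop = FALSE]),
  tan = function(tape, id, nd, tn)
    ad_rowsum_groups(tape, tn[nd$parents[1L]], nd$extra$g, nd$extra$n))

ad_concat_rows <- function(tape, ids) {
  ad_node(tape, "concat_rows", do.call(rbind, lapply(ids, ad_value, tape = tape)),
          as.integer(ids),
          extra = vapply(ids, function(i) nrow(ad_value(tape, i)), 1L))
}
ad_defop("concat_rows",
  bwd = function(nd, g, tape, need) {
    ends <- cumsum(nd$extra); starts <- ends - nd$extra + 1L
    lapply(seq_along(nd$parents), function(k)
      if (need[k]) g[starts[k]:ends[k], , drop = FALSE] else NULL)
  },
  tan = function(tape, id, nd, tn) {
    ts <- tn[nd$parents]
    if (any(ts == 0L))
      for (k in which(ts == 0L)) {
        v <- ad_value(tape, nd$parents[k])
        ts[k] <- ad_const(tape, matrix(0, nrow(v), ncol(v)))
      }
    ad_concat_rows(tape, ts)
  })

ad_concat_cols <- function(tape, ids) {
  ad_node(tape, "concat_cols", do.call(cbind, lapply(ids, ad_value, tape = tape)),
          as.integer(ids),
          extra = vapply(ids, function(i) ncol(ad_value(tape, i)), 1L))
}
ad_defop("concat_cols",
  bwd = function(nd, g, tape, need) {
    ends <- cumsum(nd$extra); starts <- ends - nd$extra + 1L
    lapply(seq_along(nd$parents), function(k)
      if (need[k]) g[, starts[k]:ends[k], drop = FALSE] else NULL)
  },
  tan = function(tape, id, nd, tn) {
    ts <- tn[nd$parents]
    if (any(ts == 0L))
      for (k in which(ts == 0L)) {
        v <- ad_value(tape, nd$parents[k])
        ts[k] <- ad_const(tape, matrix(0, nrow(v), ncol(v)))
      }
    ad_concat_cols(tape, ts)
  })

ad_reshape <- function(tape, a, nr, nc) {
  v <- ad_value(tape, a)
  ad_node(tape, "reshape", matrix(v, nr, nc), a,
          extra = c(nrow(v), ncol(v)))
}
ad_defop("reshape",
  bwd = function(nd, g, tape, need)
    list(matrix(g, nd$extra[1L], nd$extra[2L])),
  tan = function(tape, id, nd, tn) {
    v <- ad_value(tape, id)
    ad_reshape(tape, tn[nd$parents[1L]], nrow(v), ncol(v))
  })

# -- row/column scaling ---------------------------------------------------

ad_scale_rows <- function(tape, a, v) {
  va <- ad_value(tape, a); vv <- ad_value(tape, v)
  ad_node(tape, "scale_rows", va * as.vector(vv), c(a, v))
}
ad_defop("scale_rows",
  bwd = function(nd, g, tape, need) {
    va <- ad_value(tape, nd$parents[1L])
    vv <- as.vector(ad_value(tape, nd$parents[2L]))
    list(if (need[1L]) g * vv else NULL,
         if (need[2L]) matrix(.rowSums(g * va, nrow(g), ncol(g)), ncol = 1L)
         else NULL)
  },
  tan = function(tape, id, nd, tn) {
    a <- nd$parents[1L]; v <- nd$parents[2L]
    t1 <- if (tn[a] != 0L) ad_scale_rows(tape, tn[a], v) else 0L
    t2 <- if (tn[v] != 0L) ad_scale_rows(tape, a, tn[v]) else 0L
    tan_add(tape, t1, t2)
  })

ad_scale_cols <- function(tape, a, w) {
  va <- ad_value(tape, a); vw <- as.vector(ad_value(tape, w))
  ad_node(tape, "scale_cols", va * rep(vw, each = nrow(va)), c(a, w))
}
ad_defop("scale_cols",
  bwd = function(nd, g, tape, need) {
    va <- ad_value(tape, nd$parents[1L])
    vw <- as.vector(ad_value(tape, nd$parents[2L]))
    list(if (need[1L]) g * rep(vw, each = nrow(g)) else NULL,
         if (need[2L]) matrix(.colSums(g * va, nrow(g), ncol(g)), nrow = 1L)
         else NULL)
  },
  tan = function(tape, id, nd, tn) {
    a <- nd$parents[1L]; w <- nd$parents[2L]
    t1 <- if (tn[a] != 0L) ad_scale_cols(tape, tn[a], w) else 0L
    t2 <- if (tn[w] != 0L) ad_scale_cols(tape, a, tn[w]) else 0L
    tan_add(tape, t1, t2)
  })

ad_addbias <- function(tape, a, b) {
  va <- ad_value(tape, a); vb <- as.vector(ad_value(tape, b))
  ad_node(tape, "addbias", va + rep(vb, each = nrow(va)), c(a, b))
}
ad_defop("addbias",
  bwd = function(nd, g, tape, need)
    list(g, matrix(.colSums(g, nrow(g), ncol(g)), nrow = 1L)),
  tan = function(tape, id, nd, tn) {
    a <- nd$parents[1L]; b <- nd$parents[2L]
    if (tn[b] == 0L) return(tn[a])
    if (tn[a] == 0L) {
      v <- ad_value(tape, a)
      return(ad_addbias(tape, ad_const(tape, matrix(0, nrow(v), ncol(v))),
                        tn[b]))
    }
    ad_addbias(tape, tn[a], tn[b])
  })

# -- elementwise nonlinearities ------------------------------------------

ad_square <- function(tape, a) ad_node(tape, "square", ad_value(tape, a)^2, a)
ad_defop("square",
  bwd = function(nd, g, tape, need)
    list(2 * g * ad_value(tape, nd$parents[1L])),
  tan = function(tape, id, nd, tn)
    ad_smul(tape, ad_mul(tape, nd$parents[1L], tn[nd$parents[1L]]), 2))

ad_sqrt <- function(tape, a) ad_node(tape, "sqrt", sqrt(ad_value(tape, a)), a)
ad_defop("sqrt",
  bwd = function(nd, g, tape, need) list(g * (0.5 / nd$value)),
  tan = function(tape, id, nd, tn)
    ad_mul(tape, tn[nd$parents[1L]],
           ad_smul(tape, ad_recip(tape, id), 0.5)))

ad_recip <- function(tape, a) ad_node(tape, "recip", 1 / ad_value(tape, a), a)
ad_defop("recip",
  bwd = function(nd, g, tape, need) list(-g * nd$value^2),
  tan = function(tape, id, nd, tn)
    ad_neg(tape, ad_mul(tape, tn[nd$parents[1L]], ad_square(tape, id))))

ad_exp <- function(tape, a) ad_node(tape, "exp", exp(ad_value(tape, a)), a)
ad_defop("exp",
  bwd = function(nd, g, tape, need) list(g * nd$value),
  tan = function(tape, id, nd, tn)
    ad_mul(tape, tn[nd$parents[1L]], id))

# activation phi(x); derivatives supplied by act_d1/act_d2 (networks.R)
ad_act <- function(tape, name, a)
  ad_node(tape, "act", act_val(name, ad_value(tape, a)), a, extra = name)
ad_defop("act",
  bwd = function(nd, g, tape, need)
    list(g * act_d1(nd$extra, ad_value(tape, nd$parents[1L]))),
  tan = function(tape, id, nd, tn)
    ad_mul(tape, tn[nd$parents[1L]], ad_actd(tape, nd$extra, nd$parents[1L])))

ad_actd <- function(tape, name, a)
  ad_node(tape, "actd", act_d1(name, ad_value(tape, a)), a, extra = name)
ad_defop("actd",
  bwd = function(nd, g, tape, need)
    list(g * act_d2(nd$extra, ad_value(tape, nd$parents[1L]))),
  tan = function(tape, id, nd, tn)
    stop("third-order differentiation is not supported"))

# smooth radial envelope s(r) (switch_fn in neighbor_env) and its derivative
ad_switch <- function(tape, r, rs, rc) {
  v <- ad_value(tape, r)
  ad_node(tape, "switch", matrix(switch_fn(v, rs, rc), nrow(v), ncol(v)), r,
          extra = c(rs, rc))
}
ad_defop("switch",
  bwd = function(nd, g, tape, need)
    list(g * switch_fn(ad_value(tape, nd$parents[1L]),
                       nd$extra[1L], nd$extra[2L], deriv = 1L)),
  tan = function(tape, id, nd, tn)
    ad_mul(tape, tn[nd$parents[1L]],
           ad_switchd(tape, nd$parents[1L], nd$extra[1L], nd$extra[2L])))

ad_switchd <- function(tape, r, rs, rc) {
  v <- ad_value(tape, r)
  ad_node(tape, "switchd",
          matrix(switch_fn(v, rs, rc, deriv = 1L), nrow(v), ncol(v)), r,
          extra = c(rs, rc))
}
ad_defop("switchd",
  bwd = function(nd, g, tape, need)
    list(g * switch_fn(ad_value(tape, nd$parents[1L]),
                       nd$extra[1L], nd$extra[2L], deriv = 2L)),
  tan = function(tape, id, nd, tn)
    stop("third-order differentiation is not supported"))

# quintic interpolation weight bracket w(u) of the pair-potential blend
ad_polyswitch <- function(tape, u) {
  v <- ad_value(tape, u)
  ad_node(tape, "polyswitch", matrix(poly_switch(v), nrow(v), ncol(v)), u)
}
ad_defop("polyswitch",
  bwd = function(nd, g, tape, need)
    list(g * poly_switch(ad_value(tape, nd$parents[1L]), deriv = 1L)),
  tan = function(tape, id, nd, tn)
    ad_mul(tape, tn[nd$parents[1L]], ad_polyswitchd(tape, nd$parents[1L])))

ad_polyswitchd <- function(tape, u) {
  v <- ad_value(tape, u)
  ad_node(tape, "polyswitchd",
          matrix(poly_switch(v, deriv = 1L), nrow(v), ncol(v)), u)
}
ad_defop("polyswitchd",
  bwd = function(nd, g, tape, need)
    list(g * poly_switch(ad_value(tape, nd$parents[1L]), deriv = 2L)),
  tan = function(tape, id, nd, tn)
    stop("third-order differentiation is not supported"))

ad_softmax_rows <- function(tape, a) {
  v <- ad_value(tape, a)
  m <- v - apply(v, 1L, max)
  e <- exp(m)
  ad_node(tape, "softmax_rows", e / .rowSums(e, nrow(e), ncol(e)), a)
}
ad_defop("softmax_rows",
  bwd = function(nd, g, tape, need) {
    p <- nd$value
    pg <- p * g
    list(pg - p * .rowSums(pg, nrow(p), ncol(p)))
  },
  tan = function(tape, id, nd, tn) {
    ta <- tn[nd$parents[1L]]
    pt <- ad_mul(tape, id, ta)
    ad_sub(tape, pt, ad_scale_rows(tape, id, ad_rowsums(tape, pt)))
  })

# tabulated per-interval quintic (compression module); bwd uses the exact
# polynomial derivative, tangents likewise
ad_tab <- function(tape, x, tab)
  ad_node(tape, "tab", tab_eval(tab, as.vector(ad_value(tape, x))), x,
          extra = tab)
ad_defop("tab",
  bwd = function(nd, g, tape, need) {
    d <- tab_eval(nd$extra, as.vector(ad_value(tape, nd$parents[1L])),
                  deriv = 1L)
    list(matrix(.rowSums(g * d, nrow(g), ncol(g)), ncol = 1L))
  },
  tan = function(tape, id, nd, tn)
    ad_scale_rows(tape, ad_tabd(tape, nd$parents[1L], nd$extra),
                  tn[nd$parents[1L]]))

ad_tabd <- function(tape, x, tab)
  ad_node(tape, "tabd", tab_eval(tab, as.vector(ad_value(tape, x)), deriv = 1L),
          x, extra = tab)
ad_defop("tabd",
  bwd = function(nd, g, tape, need) {
    d2 <- tab_eval(nd$extra, as.vector(ad_value(tape, nd$parents[1L])),
                   deriv = 2L)
    list(matrix(.rowSums(g * d2, nrow(g), ncol(g)), ncol = 1L))
  },
  tan = function(tape, id, nd, tn)
    stop("third-order differentiation is not supported"))

# pairwise-potential table u_pair(r), C2 natural cubic spline (models module)
ad_pairtab <- function(tape, r, tab)
  ad_node(tape, "pairtab", as_mat(tab$f(as.vector(ad_value(tape, r)))), r,
          extra = tab)
ad_defop("pairtab",
  bwd = function(nd, g, tape, need)
    list(g * nd$extra$f(as.vector(ad_value(tape, nd$parents[1L])), deriv = 1L)),
  tan = function(tape, id, nd, tn)
    stop("pair-table terms are not differentiated to second order"))

# fused per-atom bilinear contraction of the two-body embedding descriptor:
# for each atom a with pair rows idx, D[a, ] = coef * vec((G'Ra)(H'Rb)')
# (column-major vec of the M x M< matrix).  One node replaces the per-atom
# slice/transpose/matmul chain; rows: list of pair-row indices per atom.
quad_value <- function(vG, vRa, vRb, vH, rows, n, coef) {
  m <- ncol(vG); mlt <- ncol(vH)
  val <- matrix(0, n, m * mlt)
  for (a in seq_len(n)) {
    idx <- rows[[a]]
    if (is.null(idx) || length(idx) == 0L) next
    A <- crossprod(vG[idx, , drop = FALSE], vRa[idx, , drop = FALSE])
    B <- crossprod(vH[idx, , drop = FALSE], vRb[idx, , drop = FALSE])
    val[a, ] <- coef * as.vector(tcrossprod(A, B))
  }
  val
}

ad_quadcontract <- function(tape, G, Ra, Rb, H, rows, n, coef) {
  v <- quad_value(ad_value(tape, G), ad_value(tape, Ra), ad_value(tape, Rb),
                  ad_value(tape, H), rows, n, coef)
  ad_node(tape, "quadcontract", v, c(G, Ra, Rb, H),
          extra = list(rows = rows, n = n, coef = coef))
}
ad_defop("quadcontract",
  bwd = function(nd, g, tape, need) {
    vG <- ad_value(tape, nd$parents[1L])
    vRa <- ad_value(tape, nd$parents[2L])
    vRb <- ad_value(tape, nd$parents[3L])
    vH <- ad_value(tape, nd$parents[4L])
    rows <- nd$extra$rows; coef <- nd$extra$coef
    m <- ncol(vG); mlt <- ncol(vH)
    dG <- if (need[1L]) vG * 0
    dRa <- if (need[2L]) vRa * 0
    dRb <- if (need[3L]) vRb * 0
    dH <- if (need[4L]) vH * 0
    for (a in seq_len(nd$extra$n)) {
      idx <- rows[[a]]
      if (is.null(idx) || length(idx) == 0L) next
      Gi <- vG[idx, , drop = FALSE]; Rai <- vRa[idx, , drop = FALSE]
      Rbi <- vRb[idx, , drop = FALSE]; Hi <- vH[idx, , drop = FALSE]
      dD <- matrix(g[a, ], m, mlt) * coef
      A <- crossprod(Gi, Rai)
      B <- crossprod(Hi, Rbi)
      dA <- dD %*% B                 # M x 4
      dB <- crossprod(dD, A)         # M< x 4
      if (need[1L]) dG[idx, ] <- dG[idx, ] + tcrossprod(Rai, dA)
      if (need[2L]) dRa[idx, ] <- dRa[idx, ] + Gi %*% dA
      if (need[3L]) dRb[idx, ] <- dRb[idx, ] + Hi %*% dB
      if (need[4L]) dH[idx, ] <- dH[idx, ] + tcrossprod(Rbi, dB)
    }
    list(dG, dRa, dRb, dH)
  },
  tan = function(tape, id, nd, tn) {
    p <- nd$parents
    e <- nd$extra
    acc <- 0L
    for (k in 1:4) {
      if (tn[p[k]] == 0L) next
      args <- as.list(p)
      args[[k]] <- tn[p[k]]
      t_k <- ad_quadcontract(tape, args[[1L]], args[[2L]], args[[3L]],
                             args[[4L]], e$rows, e$n, e$coef)
      acc <- tan_add(tape, acc, t_k)
    }
    acc
  })

# Reverse sweep ------------------------------------------------------------

#' @noRd
ad_backward <- function(tape, out, wrt, mask_off = NULL) {
  wrt <- unlist(wrt)
  # mask_off: leaf ids whose gradients are not wanted in this sweep; their
  # needs flags are cleared so e.g. weight-gradient matmuls are skipped
  if (!is.null(mask_off)) {
    mask_off <- unlist(mask_off)
    old_needs <- tape$needs[mask_off]
    tape$needs[mask_off] <- FALSE
    on.exit(tape$needs[mask_off] <- old_needs)
  }
  stopifnot(identical(dim(ad_value(tape, out)), c(1L, 1L)))
  grads <- vector("list", tape$n)
  grads[[out]] <- matrix(1, 1L, 1L)
  for (id in seq.int(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    if (nd$op == "leaf") next
    need <- tape$needs[nd$parents]
    if (!any(need)) next
    pg <- get(nd$op, envir = AD_OPS)$bwd(nd, g, tape, need)
    for (k in seq_along(nd$parents)) {
      if (!need[k] || is.null(pg[[k]])) next
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[id] <- list(NULL)
  }
  out <- grads[wrt]
  for (k in seq_along(out))
    if (is.null(out[[k]])) {
      v <- ad_value(tape, wrt[k])
      out[[k]] <- matrix(0, nrow(v), ncol(v))
    }
  names(out) <- names(wrt)
  out
}

# Forward tangent replay ----------------------------------------------------
# seeds: named list, names = node ids (as character), values = tangent
# matrices.  Returns the node id of the tangent of `out` (0 if identically
# zero).  The tangent graph is made of ordinary tape primitives, so
# ad_backward over it yields exact mixed second derivatives.

#' @noRd
ad_jvp <- function(tape, out, seeds) {
  n0 <- tape$n
  tn <- integer(n0)
  seed_ids <- as.integer(names(seeds))
  for (id in seq_len(n0)) {
    nd <- tape$nodes[[id]]
    if (nd$op == "leaf") {
      k <- match(id, seed_ids)
      if (!is.na(k)) tn[id] <- ad_const(tape, as_mat(seeds[[k]]))
      next
    }
    if (!any(tn[nd$parents] > 0L)) next
    rule <- get(nd$op, envir = AD_OPS)$tan
    if (is.null(rule)) stop("no tangent rule for op ", nd$op)
    tid <- rule(tape, id, nd, tn)
    tn[id] <- tid
  }
  if (out > n0) stop("output created after tangent replay")
  tn[out]
}
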