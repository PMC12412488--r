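# Independent brute-force oracles. These deliberately re-derive results
# with plain loops and none of the package's vectorized code paths.

# all bond angles of a molecule by double loop over bond pairs
oracle_angles <- function(bonds, n_atoms) {
  out <- character()
  m <- nrow(bonds)
  if (m < 2) return(out)
  for (b1 in seq_len(m - 1)) {
    for (b2 in (b1 + 1):m) {
      p1 <- c(bonds$i[b1], bonds$j[b1])
      p2 <- c(bonds$i[b2], bonds$j[b2])
      shared <- intersect(p1, p2)
      if (length(shared) == 1) {
        u <- setdiff(p1, shared); w <- setdiff(p2, shared)
        out <- c(out, paste(min(u, w), shared, max(u, w), sep = "-"))
      }
    }
  }
  sort(unique(out))
}

# all dihedrals by double loop over angle pairs sharing a central bond
oracle_dihedrals <- function(bonds, n_atoms) {
  m <- nrow(bonds)
  adj <- lapply(seq_len(n_atoms), function(v) {
    c(bonds$j[bonds$i == v], bonds$i[bonds$j == v])
  })
  out <- character()
  for (b in seq_len(m)) {
    v <- bonds$i[b]; w <- bonds$j[b]
    for (u in adj[[v]]) {
      for (x in adj[[w]]) {
        if (u == w || x == v || u == x) next
        quad <- c(u, v, w, x)
        rquad <- rev(quad)
        if (rquad[1] < quad[1] ||
            (rquad[1] == quad[1] && rquad[2] < quad[2])) quad <- rquad
        out <- c(out, paste(quad, collapse = "-"))
      }
    }
  }
  sort(unique(out))
}

# plain-loop single-molecule encoder, mirroring the update equations
# element by element (used to cross-check the vectorized forward pass)
oracle_forward <- function(params, graph, feats, config) {
  relu <- function(x) pmax(x, 0)
  lin <- function(p, X) sweep(X %*% p$W, 2, p$b, `+`)
  ln <- function(x, g, b) {
    if (!config$layernorm) return(x)
    for (r in seq_len(nrow(x))) {
      mu <- mean(x[r, ]); v <- mean((x[r, ] - mu)^2)
      x[r, ] <- ((x[r, ] - mu) / sqrt(v + 1e-5)) * g + b
    }
    x
  }
  combine <- function(par, H, A) {
    z <- (1 + par$eps) * H + A
    u <- sweep(relu(sweep(z %*% par$W1, 2, par$b1, `+`)) %*% par$W2, 2,
               par$b2, `+`)
    if (config$residual) u <- u + H
    ln(u, par$ln_g, par$ln_b)
  }
  n <- graph$n_atoms; m <- nrow(graph$bonds); a <- nrow(graph$angles)
  HA <- lin(params$emb$atom, feats$x_atom)
  HB <- lin(params$emb$bond, feats$x_bond)
  HG <- lin(params$emb$angle, feats$x_angle)
  ED <- lin(params$emb$dihedral, feats$x_dihedral)
  h <- params$hidden
  for (t in seq_len(config$K)) {
    if (config$use_angle_level && config$use_dihedral_level) {
      AG <- matrix(0, a, h)
      ie <- graph$i_edges
      for (e in seq_len(nrow(ie))) {
        AG[ie$dst_angle[e], ] <- AG[ie$dst_angle[e], ] +
          HG[ie$src_angle[e], ] + ED[ie$dihedral[e], ]
      }
      if (config$graphnorm) AG <- AG / sqrt(max(a, 1))
      HG <- combine(params$layers[[t]]$I, HG, AG)
    }
    if (config$use_angle_level) {
      AB <- matrix(0, m, h)
      he <- graph$h_edges
      for (e in seq_len(nrow(he))) {
        AB[he$dst_bond[e], ] <- AB[he$dst_bond[e], ] +
          HB[he$src_bond[e], ] + HG[he$angle[e], ]
      }
      if (config$graphnorm) AB <- AB / sqrt(max(m, 1))
      HB <- combine(params$layers[[t]]$H, HB, AB)
    }
    AA <- matrix(0, n, h)
    ge <- graph$g_edges
    for (e in seq_len(nrow(ge))) {
      AA[ge$dst[e], ] <- AA[ge$dst[e], ] + HA[ge$src[e], ] +
        HB[ge$bond[e], ]
    }
    if (config$graphnorm) AA <- AA / sqrt(max(n, 1))
    HA <- combine(params$layers[[t]]$G, HA, AA)
  }
  list(h_graph = colMeans(HA), h_atom = HA)
}

# plain-loop loss recomputation from raw predictions
oracle_losses <- function(preds, geo, plan, binner) {
  out <- c(length = 0, angle = 0, dihedral = 0, distance = 0)
  if (length(plan$masked_bonds) > 0) {
    s <- 0
    for (k in seq_along(plan$masked_bonds)) {
      s <- s + (preds$length[k] - geo$lengths[plan$masked_bonds[k]])^2
    }
    out[["length"]] <- s / length(plan$masked_bonds)
  }
  ok <- which(!geo$angle_degenerate[plan$masked_angles])
  if (length(ok) > 0) {
    s <- 0
    for (k in ok) {
      s <- s + (preds$angle[k] - geo$angles[plan$masked_angles[k]])^2
    }
    out[["angle"]] <- s / length(ok)
  }
  ok <- which(!geo$dihedral_degenerate[plan$masked_dihedrals])
  if (length(ok) > 0) {
    s <- 0
    for (k in ok) {
      th <- geo$dihedrals[plan$masked_dihedrals[k]]
      s <- s + (preds$dihedral[k, 1] - sin(th))^2 +
        (preds$dihedral[k, 2] - cos(th))^2
    }
    out[["dihedral"]] <- s / length(ok)
  }
  if (nrow(plan$dist_pairs) > 0) {
    s <- 0
    for (k in seq_len(nrow(plan$dist_pairs))) {
      d <- geo$dist_matrix[plan$dist_pairs[k, 1], plan$dist_pairs[k, 2]]
      bin <- min(binner$n_bins - 1, max(0, floor((d - binner$lower) /
                                                   binner$width)))
      logits <- preds$distance[k, ]
      p <- exp(logits - max(logits)) / sum(exp(logits - max(logits)))
      s <- s - log(p[bin + 1])
    }
    out[["distance"]] <- s / nrow(plan$dist_pairs)
  }
  out
}

# AUC by exhaustive positive/negative pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
    }
  }
  s / (length(pos) * length(neg))
}

# best-rotation RMSD by direct numeric minimization over Euler angles
oracle_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) mean(rowSums((A - B %*% rotmat(ang))^2))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(0, 0, pi / 2), c(pi, 0, 0), c(1, 1, 1),
                     c(-1, 2, 0.5), c(2, -1, 2))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# Davies-Bouldin from first principles
oracle_db <- function(X, labels) {
  lv <- unique(labels)
  cent <- lapply(lv, function(l) colMeans(X[labels == l, , drop = FALSE]))
  S <- vapply(seq_along(lv), function(k) {
    rows <- X[labels == lv[k], , drop = FALSE]
    mean(apply(rows, 1, function(r) sqrt(sum((r - cent[[k]])^2))))
  }, 0)
  worst <- vapply(seq_along(lv), function(i) {
    max(vapply(seq_along(lv)[-i], function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, 0))
  }, 0)
  mean(worst)
}
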