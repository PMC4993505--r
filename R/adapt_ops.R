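# The four local mesh-adaptation operations: edge refinement, node
# elimination, edge swapping and node displacement.  All of them consume and
# return a pair (mesh, der3): the per-element third-derivative estimates of
# the hierarchical correction are frozen during a sweep -- children of a
# split inherit them, merged or flipped elements take area-weighted averages
# -- and are recomputed from a fresh solve between sweeps.
#
# Every operation preserves: positive triangle orientation, region-label
# conformity and boundary/interface-tag integrity (tagged edges are split
# with their tag, merged only along straight runs of the same tag, never
# flipped, and their nodes only slide along their own line).

# norms of the centred cubic on triangles given by raw coordinates
cubic_norms_xy <- function(p1, p2, p3, der3) {
  n <- nrow(p1)
  if (n == 0) return(list(l2sq = numeric(0), h1sq = numeric(0)))
  q <- tri_quadrature(7)
  x21 <- p2[, 1] - p1[, 1]; y21 <- p2[, 2] - p1[, 2]
  x31 <- p3[, 1] - p1[, 1]; y31 <- p3[, 2] - p1[, 2]
  detJ <- abs(x21 * y31 - x31 * y21)
  cx <- (p1[, 1] + p2[, 1] + p3[, 1]) / 3
  cy <- (p1[, 2] + p2[, 2] + p3[, 2]) / 3
  l2 <- 0; h1 <- 0
  for (blk in seq_len(ncol(der3) / 4L)) {
    a <- der3[, 4 * blk - 3]; b <- der3[, 4 * blk - 2]
    cc <- der3[, 4 * blk - 1]; d <- der3[, 4 * blk]
    for (qi in seq_along(q$w)) {
      X <- p1[, 1] + q$xi[qi] * x21 + q$eta[qi] * x31 - cx
      Y <- p1[, 2] + q$xi[qi] * y21 + q$eta[qi] * y31 - cy
      cval <- a / 6 * X^3 + b / 2 * X^2 * Y + cc / 2 * X * Y^2 + d / 6 * Y^3
      gxv <- a / 2 * X^2 + b * X * Y + cc / 2 * Y^2
      gyv <- b / 2 * X^2 + cc * X * Y + d / 2 * Y^2
      l2 <- l2 + q$w[qi] * cval^2
      h1 <- h1 + q$w[qi] * (gxv^2 + gyv^2)
    }
  }
  list(l2sq = l2 * detJ, h1sq = h1 * detJ)
}

elem_l2sq <- function(mesh, der3) {
  cubic_norms(mesh$nodes, mesh$tri, der3)$l2sq
}
elem_h1sq <- function(mesh, der3) {
  cubic_norms(mesh$nodes, mesh$tri, der3)$h1sq
}

# map from edge keys of tagged edges to their tag
tag_map <- function(mesh) {
  k <- edge_key(mesh$bedges[, 1], mesh$bedges[, 2])
  tags <- mesh$btag
  names(tags) <- as.character(k)
  tags
}

#' Edge refinement sweep
#'
#' For every mesh edge the patch of incident elements is compared against
#' its share of the global error target (proportional to the patch area).
#' Over-target edges whose predicted post-split patch error is closer to the
#' target are cut at their midpoint; triangles with one, two or three marked
#' edges are subdivided into two, three or four children (tagged edges are
#' split with their tag, children inherit the parent's derivative
#' estimates).
#'
#' @param mesh a `pnp_mesh`.
#' @param der3 m x 4 per-element third-derivative estimates (from
#'   [hierarchical_correction()]).
#' @param targets an [error_targets()].
#' @param max_marks optional cap on the number of edges cut in one sweep.
#' @return list with the new `mesh`, `der3`, and `n_marked`.
#' @export
refine_edges <- function(mesh, der3, targets, max_marks = Inf) {
  ed <- mesh_edges(mesh)
  l2 <- elem_l2sq(mesh, der3)
  areas <- mesh_areas(mesh)
  E <- nrow(ed$edges)
  t1 <- ed$edge_tri[, 1]; t2 <- ed$edge_tri[, 2]
  has2 <- t2 > 0L
  perr <- l2[t1] + ifelse(has2, l2[pmax(t2, 1L)], 0)
  parea <- areas[t1] + ifelse(has2, areas[pmax(t2, 1L)], 0)
  ptarget <- targets$patch_target(parea)
  cand <- which(perr > ptarget)
  if (!length(cand)) return(list(mesh = mesh, der3 = der3, n_marked = 0L))
  # predicted post-split patch error: children of the incident triangles
  pred <- numeric(length(cand))
  for (side in 1:2) {
    tt <- if (side == 1) t1[cand] else t2[cand]
    ok <- tt > 0L
    if (!any(ok)) next
    tri <- mesh$tri[tt[ok], , drop = FALSE]
    ea <- ed$edges[cand[ok], 1]; eb <- ed$edges[cand[ok], 2]
    # third vertex of each triangle (not on the edge)
    third <- integer(length(ea))
    for (j in 1:3) {
      is3 <- tri[, j] != ea & tri[, j] != eb
      third[is3] <- tri[is3, j]
    }
    A <- mesh$nodes[ea, , drop = FALSE]
    B <- mesh$nodes[eb, , drop = FALSE]
    C <- mesh$nodes[third, , drop = FALSE]
    M <- (A + B) / 2
    d3 <- der3[tt[ok], , drop = FALSE]
    n1 <- cubic_norms_xy(A, M, C, d3)$l2sq
    n2 <- cubic_norms_xy(M, B, C, d3)$l2sq
    pred[ok] <- pred[ok] + n1 + n2
  }
  keep <- abs(pred - ptarget[cand]) < abs(perr[cand] - ptarget[cand])
  # never split edges of near-degenerate triangles (rounding safety)
  amin <- pmin(areas[t1[cand]], ifelse(has2[cand], areas[pmax(t2[cand], 1L)],
                                       Inf))
  el <- mesh$nodes[ed$edges[cand, 1], , drop = FALSE] -
    mesh$nodes[ed$edges[cand, 2], , drop = FALSE]
  elen2 <- rowSums(el^2)
  keep <- keep & amin > 1e-9 * elen2 & elen2 > 0
  marked <- cand[keep]
  if (length(marked) > max_marks) {
    sc <- (perr[marked] / ptarget[marked])
    marked <- marked[order(sc, decreasing = TRUE)[seq_len(max_marks)]]
  }
  if (!length(marked)) return(list(mesh = mesh, der3 = der3, n_marked = 0L))
  mesh2 <- apply_edge_splits(mesh, der3, ed, marked)
  list(mesh = mesh2$mesh, der3 = mesh2$der3, n_marked = length(marked))
}

# subdivide all triangles incident to the marked edges (1/2/3-edge cases)
apply_edge_splits <- function(mesh, der3, ed, marked) {
  n0 <- nrow(mesh$nodes)
  # create midpoints
  mid_id <- integer(nrow(ed$edges))
  mid_id[marked] <- n0 + seq_along(marked)
  A <- mesh$nodes[ed$edges[marked, 1], , drop = FALSE]
  B <- mesh$nodes[ed$edges[marked, 2], , drop = FALSE]
  nodes <- rbind(mesh$nodes, (A + B) / 2)
  # tagged-edge bookkeeping
  tm <- tag_map(mesh)
  mk <- as.character(edge_key(ed$edges[marked, 1], ed$edges[marked, 2]))
  tagged_marked <- mk %in% names(tm)
  bed <- mesh$bedges; btg <- mesh$btag
  if (any(tagged_marked)) {
    bkeys <- as.character(edge_key(bed[, 1], bed[, 2]))
    drop <- bkeys %in% mk[tagged_marked]
    addA <- ed$edges[marked[tagged_marked], 1]
    addB <- ed$edges[marked[tagged_marked], 2]
    addM <- mid_id[marked[tagged_marked]]
    addtag <- unname(tm[mk[tagged_marked]])
    bed <- rbind(bed[!drop, , drop = FALSE],
                 cbind(addA, addM), cbind(addM, addB))
    btg <- c(btg[!drop], addtag, addtag)
  }
  # per-triangle marked local edges (local edge j is opposite vertex j)
  mflag <- logical(nrow(ed$edges)); mflag[marked] <- TRUE
  tm3 <- matrix(mflag[ed$tri_edge], ncol = 3)
  cnt <- rowSums(tm3)
  aff <- which(cnt > 0)
  keep_tri <- cnt == 0
  new_tri <- vector("list", length(aff))
  new_reg <- vector("list", length(aff))
  new_d3 <- vector("list", length(aff))
  for (ii in seq_along(aff)) {
    t <- aff[ii]
    v <- mesh$tri[t, ]
    mids <- mid_id[ed$tri_edge[t, ]]   # midpoint of edge opposite v[j] (0 if unsplit)
    mk3 <- tm3[t, ]
    if (cnt[t] == 3L) {
      ch <- rbind(c(v[1], mids[3], mids[2]),
                  c(mids[3], v[2], mids[1]),
                  c(mids[2], mids[1], v[3]),
                  c(mids[1], mids[2], mids[3]))
    } else if (cnt[t] == 1L) {
      j <- which(mk3)
      # edge opposite v[j]: (v[j1], v[j2]) in ccw order
      j1 <- j %% 3L + 1L; j2 <- j1 %% 3L + 1L
      ch <- rbind(c(v[j], v[j1], mids[j]),
                  c(v[j], mids[j], v[j2]))
    } else {
      # two marked edges, opposite v[ja] and v[jb]; both contain the shared
      # apex v[jc]: apex triangle + quad cut along its shorter diagonal
      js <- which(mk3); jc <- which(!mk3)
      ja <- js[1]; jb <- js[2]
      ma <- mids[ja]; mb <- mids[jb]
      va <- v[ja]; vb <- v[jb]
      dv <- function(i, j) sum((nodes[i, ] - nodes[j, ])^2)
      ch <- if (dv(va, ma) < dv(vb, mb))
        rbind(c(v[jc], ma, mb), c(va, vb, ma), c(va, ma, mb))
      else
        rbind(c(v[jc], ma, mb), c(va, vb, mb), c(vb, ma, mb))
    }
    # orientation fix
    s2 <- tri_signed_area2(nodes, ch)
    if (any(s2 == 0)) stop("refinement produced a degenerate triangle",
                           call. = FALSE)
    flip <- s2 < 0
    if (any(flip)) ch[flip, ] <- ch[flip, c(1, 3, 2)]
    new_tri[[ii]] <- ch
    new_reg[[ii]] <- rep(mesh$region[t], nrow(ch))
    new_d3[[ii]] <- der3[rep(t, nrow(ch)), , drop = FALSE]
  }
  tri <- rbind(mesh$tri[keep_tri, , drop = FALSE], do.call(rbind, new_tri))
  region <- c(mesh$region[keep_tri], unlist(new_reg))
  d3 <- rbind(der3[keep_tri, , drop = FALSE], do.call(rbind, new_d3))
  m2 <- new_pnp_mesh(nodes, tri, region, bed, btg, check = FALSE)
  list(mesh = m2, der3 = d3)
}

# --- node elimination ------------------------------------------------------

# incident triangles per vertex (list indexed by vertex id as character)
vertex_stars <- function(mesh) {
  split(rep(seq_len(nrow(mesh$tri)), 3L), as.vector(mesh$tri))
}

# ordered ring around vertex v given its star triangles; returns the ordered
# neighbour cycle (closed: first == last not repeated) or chain endpoints.
ring_around <- function(mesh, v, star) {
  k <- length(star)
  nb <- matrix(0L, k, 2)
  for (i in seq_len(k)) {
    tv <- mesh$tri[star[i], ]
    j <- which(tv == v)
    # ccw: after v comes tv[j+1], then tv[j+2]; directed edge a -> b
    a <- tv[j %% 3L + 1L]; b <- tv[(j + 1L) %% 3L + 1L]
    nb[i, ] <- c(a, b)
  }
  # link directed edges a->b into chain(s)
  from <- nb[, 1]
  chain_start <- setdiff(from, nb[, 2])
  closed <- length(chain_start) == 0
  start <- if (closed) from[1] else chain_start[1]
  ring <- start
  cur <- start
  for (i in seq_len(k)) {
    nxt <- nb[match(cur, from), 2]
    if (is.na(nxt)) break
    ring <- c(ring, nxt)
    cur <- nxt
    if (closed && cur == start) break
  }
  if (closed) ring <- ring[-length(ring)]
  list(ring = ring, closed = closed)
}

# ear-clip a polygon (vertex ids, positions taken from nodes); polygon must
# be given in ccw order.  Returns a matrix of triangles or NULL on failure.
ear_clip <- function(nodes, poly) {
  n <- length(poly)
  if (n < 3) return(NULL)
  idx <- poly
  scal <- max(apply(nodes[poly, , drop = FALSE], 2,
                    function(v) diff(range(v))))^2
  xs <- nodes[poly, 1]; ys <- nodes[poly, 2]
  a2tot <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
  floor2 <- max(1e-13 * scal, 1e-7 * a2tot)
  out <- matrix(0L, 0, 3)
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    k <- length(idx)
    best <- 0L; best_q <- -Inf
    for (i in seq_len(k)) {
      ip <- idx[(i - 2L) %% k + 1L]; ic <- idx[i]; inx <- idx[i %% k + 1L]
      a <- nodes[ip, ]; b <- nodes[ic, ]; cpt <- nodes[inx, ]
      ar2 <- (b[1] - a[1]) * (cpt[2] - a[2]) - (cpt[1] - a[1]) * (b[2] - a[2])
      if (ar2 <= floor2) next
      # no other polygon vertex inside the candidate ear
      others <- setdiff(idx, c(ip, ic, inx))
      ok <- TRUE
      for (o in others) {
        p <- nodes[o, ]
        b1 <- (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])
        b2 <- (cpt[1] - b[1]) * (p[2] - b[2]) - (p[1] - b[1]) * (cpt[2] - b[2])
        b3 <- (a[1] - cpt[1]) * (p[2] - cpt[2]) - (p[1] - cpt[1]) * (a[2] - cpt[2])
        if (b1 > 0 && b2 > 0 && b3 > 0) { ok <- FALSE; break }
      }
      if (!ok) next
      # quality: shortest-edge-to-area ratio, prefer fat ears
      l2max <- max(sum((a - b)^2), sum((b - cpt)^2), sum((cpt - a)^2))
      q <- ar2 / l2max
      if (q > best_q) { best_q <- q; best <- i }
    }
    if (best == 0L) return(NULL)
    k <- length(idx)
    ip <- idx[(best - 2L) %% k + 1L]; ic <- idx[best]; inx <- idx[best %% k + 1L]
    out <- rbind(out, c(ip, ic, inx))
    idx <- idx[-best]
  }
  ar2 <- tri_signed_area2(nodes, matrix(idx, 1, 3))
  if (ar2 <= floor2) return(NULL)
  rbind(out, idx)
}

#' Node elimination sweep
#'
#' Vertices whose surrounding patch error falls below its target share are
#' removed and their cavity retriangulated (ear clipping), provided the
#' retriangulated cavity's predicted error is closer to the target than the
#' original.  Vertices on tagged lines are only removed when their two
#' tagged edges are collinear runs of the same tag (the merged edge keeps
#' the tag); corners and junctions are never removed.  Unreferenced nodes
#' are dropped and indices remapped.
#'
#' @inheritParams refine_edges
#' @param slack only vertices with patch error below `slack` times the patch
#'   target are candidates.
#' @return list with `mesh`, `der3`, `n_removed`.
#' @export
eliminate_nodes <- function(mesh, der3, targets, slack = 0.6,
                            max_frac = 0.3) {
  l2 <- elem_l2sq(mesh, der3)
  areas <- mesh_areas(mesh)
  stars <- vertex_stars(mesh)
  nvert <- nrow(mesh$nodes)
  # tagged edges per vertex
  vb <- c(mesh$bedges[, 1], mesh$bedges[, 2])
  vbe <- split(rep(seq_len(nrow(mesh$bedges)), 2L), vb)
  perr <- vapply(stars, function(s) sum(l2[s]), 0)
  parea <- vapply(stars, function(s) sum(areas[s]), 0)
  vid <- as.integer(names(stars))
  ptar <- targets$patch_target(parea)
  cand <- vid[perr < slack * ptar]
  if (!length(cand)) return(list(mesh = mesh, der3 = der3, n_removed = 0L))
  ord <- order((perr / pmax(ptar, 1e-300))[match(cand, vid)])
  cand <- cand[ord]
  alive_tri <- rep(TRUE, nrow(mesh$tri))
  tri <- mesh$tri; region <- mesh$region; d3 <- der3
  bed <- mesh$bedges; btg <- mesh$btag; alive_b <- rep(TRUE, nrow(bed))
  dirty <- logical(nvert)
  add_tri <- list(); add_reg <- list(); add_d3 <- list()
  add_bed <- list(); add_btg <- integer(0)
  removed <- 0L
  max_removed <- max(1L, floor(max_frac * nvert))
  for (v in cand) {
    if (removed >= max_removed) break
    if (dirty[v]) next
    star <- stars[[as.character(v)]]
    if (is.null(star) || !all(alive_tri[star])) next
    tedg <- vbe[[as.character(v)]]
    tedg <- tedg[alive_b[tedg]]
    if (length(tedg) == 0L) {
      # interior vertex: single region, closed ring
      rg <- ring_around(mesh, v, star)
      if (!rg$closed) next
      tris_new <- ear_clip(mesh$nodes, rg$ring)
      if (is.null(tris_new)) next
      regv <- region[star[1]]
      d3avg <- colSums(d3[star, , drop = FALSE] * areas[star]) /
        sum(areas[star])
      newn <- cubic_norms(mesh$nodes, tris_new,
                          matrix(d3avg, nrow(tris_new), length(d3avg),
                                 byrow = TRUE))
      errn <- sum(newn$l2sq)
      tgt <- targets$patch_target(sum(areas[star]))
      if (abs(errn - tgt) > abs(sum(l2[star]) - tgt)) next
      alive_tri[star] <- FALSE
      add_tri[[length(add_tri) + 1L]] <- tris_new
      add_reg[[length(add_reg) + 1L]] <- rep(regv, nrow(tris_new))
      add_d3[[length(add_d3) + 1L]] <-
        matrix(d3avg, nrow(tris_new), length(d3avg), byrow = TRUE)
      dirty[rg$ring] <- TRUE; dirty[v] <- TRUE
      removed <- removed + 1L
    } else if (length(tedg) == 2L && btg[tedg[1]] == btg[tedg[2]]) {
      # line vertex: require collinearity of the two tagged edges
      e1 <- bed[tedg[1], ]; e2 <- bed[tedg[2], ]
      a <- setdiff(e1, v); b <- setdiff(e2, v)
      if (length(a) != 1L || length(b) != 1L) next
      u1 <- mesh$nodes[a, ] - mesh$nodes[v, ]
      u2 <- mesh$nodes[b, ] - mesh$nodes[v, ]
      cr <- u1[1] * u2[2] - u1[2] * u2[1]
      if (abs(cr) > 1e-12 * sqrt(sum(u1^2) * sum(u2^2))) next
      # split the star by region (domain-boundary vertex has one group)
      groups <- split(star, region[star])
      ok_all <- TRUE
      tris_acc <- list(); reg_acc <- integer(0); d3_acc <- list()
      err_new_tot <- 0
      for (gi in seq_along(groups)) {
        gstar <- groups[[gi]]
        rg <- ring_around(mesh, v, gstar)
        if (rg$closed) { ok_all <- FALSE; break }
        ring <- rg$ring
        # chain runs from one line neighbour to the other; closing edge is
        # the merged tagged edge (straight)
        if (!((ring[1] == a && ring[length(ring)] == b) ||
                (ring[1] == b && ring[length(ring)] == a))) {
          ok_all <- FALSE; break
        }
        if (length(ring) == 2L) { ok_all <- FALSE; break }
        tn <- ear_clip(mesh$nodes, ring)
        if (is.null(tn)) { ok_all <- FALSE; break }
        d3g <- colSums(d3[gstar, , drop = FALSE] * areas[gstar]) /
          sum(areas[gstar])
        err_new_tot <- err_new_tot +
          sum(cubic_norms(mesh$nodes, tn,
                          matrix(d3g, nrow(tn), length(d3g),
                                 byrow = TRUE))$l2sq)
        tris_acc[[gi]] <- tn
        reg_acc <- c(reg_acc, rep(region[gstar[1]], nrow(tn)))
        d3_acc[[gi]] <- matrix(d3g, nrow(tn), length(d3g), byrow = TRUE)
      }
      if (!ok_all) next
      tgt <- targets$patch_target(sum(areas[star]))
      if (abs(err_new_tot - tgt) > abs(sum(l2[star]) - tgt)) next
      alive_tri[star] <- FALSE
      alive_b[tedg] <- FALSE
      add_bed[[length(add_bed) + 1L]] <- c(a, b)
      add_btg <- c(add_btg, btg[tedg[1]])
      for (gi in seq_along(tris_acc)) {
        add_tri[[length(add_tri) + 1L]] <- tris_acc[[gi]]
        add_reg[[length(add_reg) + 1L]] <- rep(region[groups[[gi]][1]],
                                               nrow(tris_acc[[gi]]))
        add_d3[[length(add_d3) + 1L]] <- d3_acc[[gi]]
      }
      ringall <- unique(unlist(lapply(groups, function(gs)
        ring_around(mesh, v, gs)$ring)))
      dirty[ringall] <- TRUE; dirty[v] <- TRUE
      removed <- removed + 1L
    }
  }
  if (removed == 0L) return(list(mesh = mesh, der3 = der3, n_removed = 0L))
  tri2 <- rbind(tri[alive_tri, , drop = FALSE], do.call(rbind, add_tri))
  reg2 <- c(region[alive_tri], unlist(add_reg))
  d32 <- rbind(d3[alive_tri, , drop = FALSE], do.call(rbind, add_d3))
  bed2 <- bed[alive_b, , drop = FALSE]
  if (length(add_bed))
    bed2 <- rbind(bed2, matrix(unlist(add_bed), ncol = 2, byrow = TRUE))
  btg2 <- c(btg[alive_b], add_btg)
  cm <- compact_mesh(new_pnp_mesh(mesh$nodes, tri2, reg2, bed2, btg2,
                                  check = FALSE), d32)
  list(mesh = cm$mesh, der3 = cm$der3, n_removed = removed)
}

# drop unreferenced nodes and remap indices
compact_mesh <- function(mesh, der3) {
  used <- sort(unique(as.vector(mesh$tri)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  m2 <- new_pnp_mesh(mesh$nodes[used, , drop = FALSE],
                     matrix(remap[mesh$tri], ncol = 3),
                     mesh$region,
                     matrix(remap[mesh$bedges], ncol = 2),
                     mesh$btag, check = FALSE)
  list(mesh = m2, der3 = der3)
}

# --- edge swapping ---------------------------------------------------------

#' Edge swapping sweep
#'
#' An interior, untagged edge shared by two triangles is flipped when the
#' flip strictly decreases the H1-seminorm of the hierarchical correction
#' summed over the quadrilateral (the flipped pair takes the area-weighted
#' average of the old derivative estimates).  Non-convex quadrilaterals and
#' region-boundary edges are never flipped.
#'
#' @inheritParams refine_edges
#' @return list with `mesh`, `der3`, `n_flipped`.
#' @export
swap_edges <- function(mesh, der3, targets = NULL) {
  ed <- mesh_edges(mesh)
  tm <- tag_map(mesh)
  keys <- as.character(edge_key(ed$edges[, 1], ed$edges[, 2]))
  interior <- ed$edge_tri[, 2] > 0L & !(keys %in% names(tm))
  cand <- which(interior)
  if (!length(cand)) return(list(mesh = mesh, der3 = der3, n_flipped = 0L))
  h1 <- elem_h1sq(mesh, der3)
  areas <- mesh_areas(mesh)
  tri <- mesh$tri; d3 <- der3
  touched <- logical(nrow(tri))
  nflip <- 0L
  for (e in cand) {
    ta <- ed$edge_tri[e, 1]; tb <- ed$edge_tri[e, 2]
    if (touched[ta] || touched[tb]) next
    a <- ed$edges[e, 1]; b <- ed$edges[e, 2]
    va <- tri[ta, ]; vb <- tri[tb, ]
    c1 <- setdiff(va, c(a, b)); d1 <- setdiff(vb, c(a, b))
    if (length(c1) != 1L || length(d1) != 1L) next
    # proposed flip: (a,b) -> (c1,d1)
    n1 <- c(a, d1, c1); n2 <- c(b, c1, d1)
    s1 <- tri_signed_area2(mesh$nodes, matrix(n1, 1, 3))
    s2 <- tri_signed_area2(mesh$nodes, matrix(n2, 1, 3))
    if (s1 <= 0) n1 <- n1[c(1, 3, 2)]
    if (s2 <= 0) n2 <- n2[c(1, 3, 2)]
    s1 <- abs(s1); s2 <- abs(s2)
    quad2 <- 2 * (areas[ta] + areas[tb])
    if (s1 < 1e-6 * quad2 || s2 < 1e-6 * quad2) next     # non-convex / sliver
    if (abs(s1 + s2 - quad2) > 1e-9 * quad2) next        # safety
    d3avg <- (der3[ta, ] * areas[ta] + der3[tb, ] * areas[tb]) /
      (areas[ta] + areas[tb])
    newh <- sum(cubic_norms(mesh$nodes, rbind(n1, n2),
                            rbind(d3avg, d3avg))$h1sq)
    if (newh < (h1[ta] + h1[tb]) * (1 - 1e-8)) {
      tri[ta, ] <- n1; tri[tb, ] <- n2
      d3[ta, ] <- d3avg; d3[tb, ] <- d3avg
      touched[ta] <- TRUE; touched[tb] <- TRUE
      nflip <- nflip + 1L
    }
  }
  if (nflip == 0L) return(list(mesh = mesh, der3 = der3, n_flipped = 0L))
  m2 <- new_pnp_mesh(mesh$nodes, tri, mesh$region, mesh$bedges, mesh$btag,
                     check = FALSE)
  list(mesh = m2, der3 = d3, n_flipped = nflip)
}

# --- node displacement -----------------------------------------------------

#' Node displacement sweep
#'
#' Each movable vertex is relocated towards the local minimizer of the
#' patch H1-seminorm of the hierarchical correction (steepest descent with a
#' short backtracking line search; derivative estimates frozen).  Vertices
#' on tagged lines slide only along their line; corners stay fixed; no move
#' is accepted that inverts a patch triangle (checked again globally after
#' the simultaneous update, reverting offenders).
#'
#' @inheritParams refine_edges
#' @param iters number of sweeps of the whole mesh.
#' @param step0 initial step as a fraction of the shortest incident edge.
#' @return list with `mesh`, `der3`, `n_moved`.
#' @export
move_nodes <- function(mesh, der3, targets = NULL, iters = 1L, step0 = 0.25) {
  d3 <- der3
  nmoved_tot <- 0L
  for (sweep in seq_len(iters)) {
    res <- move_nodes_once(mesh, d3, step0)
    mesh <- res$mesh
    nmoved_tot <- nmoved_tot + res$n_moved
    if (res$n_moved == 0L) break
  }
  list(mesh = mesh, der3 = d3, n_moved = nmoved_tot)
}

move_nodes_once <- function(mesh, der3, step0) {
  nvert <- nrow(mesh$nodes)
  stars <- vertex_stars(mesh)
  vid <- as.integer(names(stars))
  # movability: free if on no tagged edge; slide along direction if exactly
  # two collinear same-tag edges; else fixed
  vb <- c(mesh$bedges[, 1], mesh$bedges[, 2])
  vbe <- split(rep(seq_len(nrow(mesh$bedges)), 2L), vb)
  kind <- rep(0L, nvert)      # 0 free, 1 slide, 2 fixed
  sdir <- matrix(0, nvert, 2)
  for (v in as.integer(names(vbe))) {
    ee <- vbe[[as.character(v)]]
    if (length(ee) == 2L && mesh$btag[ee[1]] == mesh$btag[ee[2]]) {
      a <- setdiff(mesh$bedges[ee[1], ], v)
      b <- setdiff(mesh$bedges[ee[2], ], v)
      u1 <- mesh$nodes[a, ] - mesh$nodes[v, ]
      u2 <- mesh$nodes[b, ] - mesh$nodes[v, ]
      cr <- u1[1] * u2[2] - u1[2] * u2[1]
      if (abs(cr) <= 1e-12 * sqrt(sum(u1^2) * sum(u2^2))) {
        kind[v] <- 1L
        sdir[v, ] <- u1 / sqrt(sum(u1^2))
      } else kind[v] <- 2L
    } else kind[v] <- 2L
  }
  nodes <- mesh$nodes
  tri <- mesh$tri
  # patch energy of vertex v with v at position p; moves that shrink any
  # incident triangle below a tenth of its current area are rejected
  patch_energy <- function(star, v, p, s2ref = NULL) {
    tt <- tri[star, , drop = FALSE]
    P1 <- nodes[tt[, 1], , drop = FALSE]
    P2 <- nodes[tt[, 2], , drop = FALSE]
    P3 <- nodes[tt[, 3], , drop = FALSE]
    for (cdx in 1:2) {
      P1[tt[, 1] == v, cdx] <- p[cdx]
      P2[tt[, 2] == v, cdx] <- p[cdx]
      P3[tt[, 3] == v, cdx] <- p[cdx]
    }
    s2 <- (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
      (P3[, 1] - P1[, 1]) * (P2[, 2] - P1[, 2])
    if (any(s2 <= 1e-12 * max(abs(s2)))) return(Inf)
    if (!is.null(s2ref) && any(s2 < 0.1 * s2ref)) return(Inf)
    sum(cubic_norms_xy(P1, P2, P3, der3[star, , drop = FALSE])$h1sq)
  }
  moved <- 0L
  newpos <- nodes
  for (iv in seq_along(vid)) {
    v <- vid[iv]
    if (v <= length(kind) && kind[v] == 2L) next
    star <- stars[[iv]]
    p0 <- nodes[v, ]
    s2ref <- 2 * mesh_areas_subset(nodes, tri, star)
    hloc <- sqrt(min(s2ref) / 2)
    e0 <- patch_energy(star, v, p0)
    if (!is.finite(e0) || e0 == 0) next
    d <- 1e-4 * hloc
    if (kind[v] == 1L) {
      u <- sdir[v, ]
      gp <- (patch_energy(star, v, p0 + d * u) -
               patch_energy(star, v, p0 - d * u)) / (2 * d)
      dir <- -gp * u
    } else {
      gx <- (patch_energy(star, v, p0 + c(d, 0)) -
               patch_energy(star, v, p0 - c(d, 0))) / (2 * d)
      gy <- (patch_energy(star, v, p0 + c(0, d)) -
               patch_energy(star, v, p0 - c(0, d))) / (2 * d)
      dir <- -c(gx, gy)
    }
    dn <- sqrt(sum(dir^2))
    if (!is.finite(dn) || dn == 0) next
    dir <- dir / dn
    accepted <- FALSE
    for (s in step0 * hloc * c(1, 0.5, 0.25, 0.1)) {
      p <- p0 + s * dir
      ev <- patch_energy(star, v, p, s2ref)
      if (is.finite(ev) && ev < e0 * (1 - 1e-10)) {
        newpos[v, ] <- p
        accepted <- TRUE
        break
      }
    }
    if (accepted) moved <- moved + 1L
  }
  if (moved == 0L)
    return(list(mesh = mesh, n_moved = 0L))
  # simultaneous update with global validity repair
  for (rep_i in 1:20) {
    s2 <- tri_signed_area2(newpos, tri)
    bad <- which(s2 <= 0)
    if (!length(bad)) break
    bv <- unique(as.vector(tri[bad, ]))
    newpos[bv, ] <- mesh$nodes[bv, ]
  }
  s2 <- tri_signed_area2(newpos, tri)
  if (any(s2 <= 0)) newpos <- mesh$nodes   # give up rather than invert
  m2 <- mesh; m2$nodes <- newpos
  list(mesh = m2, n_moved = moved)
}

mesh_areas_subset <- function(nodes, tri, idx) {
  tt <- tri[idx, , drop = FALSE]
  abs((nodes[tt[, 2], 1] - nodes[tt[, 1], 1]) *
        (nodes[tt[, 3], 2] - nodes[tt[, 1], 2]) -
        (nodes[tt[, 3], 1] - nodes[tt[, 1], 1]) *
        (nodes[tt[, 2], 2] - nodes[tt[, 1], 2])) / 2
}
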