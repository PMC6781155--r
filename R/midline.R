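# Sub-pixel midline extraction and curve straightening.
#
# The SC length of a bivalent is quantified as the length of its
# straightened midline: the binary mask is thinned to a one-pixel skeleton,
# short side branches are pruned, the longest geodesic path between skeleton
# endpoints is taken as the midline, a smoothing spline is fitted to it, the
# ends are extended along the end tangents to the mask boundary (thinning
# retracts skeleton ends by about half the ribbon width), and the spline is
# resampled at a uniform arc step.

#' Midline extraction parameters
#'
#' @param spur_px skeleton side branches shorter than this are pruned.
#' @param resample_step arc-length resampling step of the midline (px).
#' @param px_per_um pixel-to-micrometer conversion factor (instrument
#'   specific; override to match the acquisition setup).
#' @param max_spline_dev maximum allowed deviation (px) of the smoothing
#'   spline from the raw skeleton path; smoothing stiffness is relaxed until
#'   this bound holds.
#' @param max_extension_px cap on the tangent extension at each end
#'   (thinning can retract tapering ends by several half-widths).
#' @return List of class `midline_params`.
#' @export
midline_params <- function(spur_px = 5, resample_step = 0.5,
                           px_per_um = 9.8152, max_spline_dev = 1,
                           max_extension_px = 20) {
  structure(list(spur_px = spur_px, resample_step = resample_step,
                 px_per_um = px_per_um, max_spline_dev = max_spline_dev,
                 max_extension_px = max_extension_px),
            class = "midline_params")
}

shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours clockwise from north
      p2 <- shift_mat(img,  1,  0)  # N is row-1 in image terms; orientation
      p3 <- shift_mat(img,  1, -1)  # is irrelevant to thinning, any fixed
      p4 <- shift_mat(img,  0, -1)  # consistent assignment works
      p5 <- shift_mat(img, -1, -1)
      p6 <- shift_mat(img, -1,  0)
      p7 <- shift_mat(img, -1,  1)
      p8 <- shift_mat(img,  0,  1)
      p9 <- shift_mat(img,  1,  1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# Build the 8-connected weighted graph of a skeleton, prune short spurs, and
# find the longest geodesic path between endpoints. Returns NULL for an
# empty skeleton. `n_branch_points` counts vertices of degree >= 3 after
# pruning; `endpoints` is empty for a pure cycle.
skeleton_graph <- function(mask, spur_px = 5) {
  sk <- skeletonize(mask)
  px <- which(sk)
  if (length(px) == 0) return(NULL)
  H <- nrow(sk)
  rr <- ((px - 1L) %% H) + 1L
  cc <- ((px - 1L) %/% H) + 1L
  id <- seq_along(px)
  lut <- new.env(hash = TRUE)
  key <- paste(rr, cc)
  for (i in id) assign(key[i], i, envir = lut)
  look <- function(keys) vapply(keys, function(k) {
    as.integer(mget(k, envir = lut, ifnotfound = list(NA_integer_))[[1]])
  }, 1L, USE.NAMES = FALSE)
  nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
             c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in nb) {
    j <- look(paste(rr + d[1], cc + d[2]))
    has <- !is.na(j) & id < j  # each undirected edge once
    if (all(abs(d) == 1)) {
      # m-connectivity: skip a diagonal edge when either orthogonal
      # common neighbour is present (avoids staircase triangles that
      # masquerade as branch points)
      o1 <- look(paste(rr + d[1], cc))
      o2 <- look(paste(rr, cc + d[2]))
      has <- has & is.na(o1) & is.na(o2)
    }
    if (any(has)) {
      from <- c(from, id[has]); to <- c(to, j[has])
      w <- c(w, rep(sqrt(sum(d^2)), sum(has)))
    }
  }
  if (length(from) == 0) {
    # single isolated pixel(s): treat the first as a degenerate point
    return(list(coords = cbind(row = rr, col = cc),
                path_coords = cbind(row = rr[1], col = cc[1]),
                longest_path_length = 0,
                n_branch_points = 0L, endpoints = integer(0)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = id, row = rr, col = cc))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    main <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == main))
  }

  # iterative spur pruning: remove endpoint chains shorter than spur_px that
  # terminate at a branch point
  repeat {
    deg <- igraph::degree(g)
    ends <- which(deg == 1)
    if (length(ends) == 0) break
    removed_any <- FALSE
    for (e in ends) {
      if (e > igraph::vcount(g)) next
      deg <- igraph::degree(g)
      if (is.na(deg[e]) || deg[e] != 1) next
      chain <- e
      prev <- -1L
      cur <- e
      len <- 0
      repeat {
        nbs <- as.integer(igraph::neighbors(g, cur))
        nxt <- setdiff(nbs, prev)
        if (length(nxt) != 1) break
        eid <- igraph::get_edge_ids(g, c(cur, nxt[1]))
        len <- len + igraph::E(g)$weight[eid]
        prev <- cur; cur <- nxt[1]
        if (igraph::degree(g, cur) != 2) break
        chain <- c(chain, cur)
      }
      # cur is the terminus (branch point or other endpoint)
      if (len < spur_px && igraph::degree(g, cur) >= 3) {
        g <- igraph::delete_vertices(g, chain)
        removed_any <- TRUE
        break  # vertex ids shifted; restart the scan
      }
    }
    if (!removed_any) break
  }

  deg <- igraph::degree(g)
  vr <- igraph::V(g)$row; vc <- igraph::V(g)$col
  ends <- which(deg == 1)
  n_branch <- sum(deg >= 3)
  if (length(ends) == 0) {
    return(list(coords = cbind(row = vr, col = vc),
                path_coords = NULL, longest_path_length = NA_real_,
                n_branch_points = n_branch, endpoints = integer(0)))
  }
  # lexicographic endpoint order for deterministic tie-breaking
  ord <- order(vr[ends], vc[ends])
  ends <- ends[ord]
  D <- igraph::distances(g, v = ends, to = ends)
  best <- which(D == max(D[is.finite(D)]), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  sp <- igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                               output = "vpath")$vpath[[1]]
  vp <- as.integer(sp)
  list(coords = cbind(row = vr, col = vc),
       path_coords = cbind(row = vr[vp], col = vc[vp]),
       longest_path_length = max(D[is.finite(D)]),
       n_branch_points = n_branch,
       endpoints = ends)
}

#' Extract the sub-pixel midline of a bivalent mask
#'
#' Thins the mask, prunes spurs, takes the longest geodesic skeleton path,
#' fits a smoothing spline constrained to stay within
#' `params$max_spline_dev` of the skeleton, extends both ends along their
#' tangents to the mask boundary, and resamples at a uniform arc step.
#'
#' @param mask logical matrix (one bivalent).
#' @param params a [midline_params()].
#' @param graph optional precomputed result of the internal skeleton-graph
#'   step, to avoid re-thinning.
#' @return Object of class `midline`: `points` (m x 2, row/col), `s`
#'   (cumulative arc length), `total_length_px`, `total_length_um`, `step`.
#' @export
extract_midline <- function(mask, params = midline_params(), graph = NULL) {
  if (is.null(graph)) graph <- skeleton_graph(mask, spur_px = params$spur_px)
  if (is.null(graph) || length(graph$endpoints) == 0 ||
      is.null(graph$path_coords))
    stop("degenerate skeleton")
  pc <- graph$path_coords
  if (nrow(pc) < 2) stop("degenerate skeleton")
  seg <- sqrt(rowSums(diff(pc)^2))
  s <- c(0, cumsum(seg))

  if (nrow(pc) >= 8) {
    # relax stiffness until the spline tracks the skeleton to within bound
    dfs <- unique(pmin(nrow(pc) - 1, c(4, 6, 9, 14, 20, 30, 45,
                                       ceiling(nrow(pc) / 2))))
    for (df in dfs) {
      fr <- stats::smooth.spline(s, pc[, 1], df = df)
      fc <- stats::smooth.spline(s, pc[, 2], df = df)
      dev <- sqrt((stats::predict(fr, s)$y - pc[, 1])^2 +
                    (stats::predict(fc, s)$y - pc[, 2])^2)
      if (max(dev) <= params$max_spline_dev) break
    }
    tfine <- seq(0, max(s), by = 0.25)
    pts <- cbind(stats::predict(fr, tfine)$y, stats::predict(fc, tfine)$y)
  } else {
    pts <- pc
  }

  # average ribbon half-width, used to retract end extensions at rounded
  # caps (the mask of a capped tube extends ~half-width past the midline)
  hw_est <- sum(mask) / (2 * max(graph$longest_path_length, 1))
  pts <- extend_ends_into_mask(pts, mask, params$max_extension_px, hw_est)

  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  step <- params$resample_step
  su <- seq(0, L, by = step)
  if (su[length(su)] < L) su <- c(su, L)
  ru <- stats::approx(s, pts[, 1], xout = su)$y
  cu <- stats::approx(s, pts[, 2], xout = su)$y
  structure(list(points = cbind(row = ru, col = cu), s = su,
                 total_length_px = L,
                 total_length_um = to_micrometers(L, params$px_per_um),
                 px_per_um = params$px_per_um,
                 step = step),
            class = "midline")
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("midline: %.2f px (%.3f um), %d samples at %.2g px\n",
              x$total_length_px, x$total_length_um, nrow(x$points), x$step))
  invisible(x)
}

# March from both ends along the end tangents while still inside the mask
# (thinning retracts skeleton ends), then retract by the portion of the
# ribbon half-width not accounted for by the perpendicular chord at the
# boundary: a rounded end cap (chord -> 0) is retracted by a full
# half-width, a flat-ended bar (chord = full width) not at all.
extend_ends_into_mask <- function(pts, mask, max_ext, hw_est = 0) {
  H <- nrow(mask); W <- ncol(mask)
  inside <- function(p) {
    r <- round(p[1]); c_ <- round(p[2])
    r >= 1 && r <= H && c_ >= 1 && c_ <= W && isTRUE(mask[r, c_])
  }
  half_chord <- function(q, n) {
    h <- 0
    for (k in seq(0.5, max(2 * hw_est, 2), by = 0.5)) {
      if (!inside(q + k * n)) break
      h <- k
    }
    h
  }
  recenter <- function(q, v) {
    # snap q to the midpoint of the perpendicular in-mask chord, so the
    # extension follows the centerline of a curving or tapering end
    n <- c(-v[2], v[1])
    lim <- max(hw_est * 1.5, 2)
    up <- 0; dn <- 0
    for (k in seq(0.5, lim, by = 0.5)) {
      if (inside(q + k * n)) up <- k else break
    }
    for (k in seq(0.5, lim, by = 0.5)) {
      if (inside(q - k * n)) dn <- k else break
    }
    q + (up - dn) / 2 * n
  }
  one_end <- function(p_end, p_prev) {
    v <- p_end - p_prev
    nv <- sqrt(sum(v^2))
    if (nv <= 0) return(NULL)
    v <- v / nv
    v0 <- v
    ext <- NULL
    p <- p_end
    n_steps <- floor(max_ext / 0.5)
    for (k in seq_len(n_steps)) {
      q <- p + v * 0.5
      if (!inside(q)) break
      q <- recenter(q, v)
      vn <- q - p
      nv <- sqrt(sum(vn^2))
      if (nv < 1e-6) break
      vn <- vn / nv
      # the extension must keep advancing roughly along the end tangent;
      # recentering may bend it gently but never turn it back inside
      if (sum(vn * v0) < 0.5 || sum((q - p_end) * v0) <= sum((p - p_end) * v0))
        break
      v <- vn
      ext <- rbind(ext, q)
      p <- q
    }
    if (is.null(ext)) return(NULL)
    if (hw_est > 0) {
      qb <- ext[nrow(ext), ]
      n <- c(-v[2], v[1])
      w_end <- half_chord(qb, n) + half_chord(qb, -n)
      retract <- max(0, hw_est - w_end / 2)
      drop_n <- min(nrow(ext), floor(retract / 0.5))
      if (drop_n > 0) ext <- ext[seq_len(nrow(ext) - drop_n), , drop = FALSE]
      if (nrow(ext) == 0) return(NULL)
    }
    ext
  }
  m <- nrow(pts)
  a <- min(5, m - 1)
  head_ext <- one_end(pts[1, ], pts[1 + a, ])
  tail_ext <- one_end(pts[m, ], pts[m - a, ])
  out <- pts
  if (!is.null(head_ext)) out <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  out
}

#' Convert a pixel length to micrometers
#'
#' @param length_px length in pixels.
#' @param px_per_um conversion factor (pixels per micrometer, > 0).
#' @return `length_px / px_per_um`.
#' @export
to_micrometers <- function(length_px, px_per_um = 9.8152) {
  if (!is.numeric(px_per_um) || any(px_per_um <= 0))
    stop("px_per_um must be positive")
  length_px / px_per_um
}

# Vectorized bilinear interpolation; coordinates are clamped to the image.
bilinear_sample <- function(mat, r, c_) {
  H <- nrow(mat); W <- ncol(mat)
  clamped <- any(r < 1 | r > H | c_ < 1 | c_ > W)
  r <- pmin(pmax(r, 1), H)
  c_ <- pmin(pmax(c_, 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c_), W - 1)
  fr <- r - r0; fc <- c_ - c0
  v <- mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    mat[cbind(r0 + 1, c0 + 1)] * fr * fc
  attr(v, "clamped") <- clamped
  v
}

#' Straighten an image along a midline
#'
#' Samples the image perpendicular to the midline at each resampled point
#' with bilinear interpolation, producing a ribbon of height
#' `2 * half_width + 1` and one column per midline sample. Useful both for
#' the straightened visual output and for profiling signal along the SC.
#'
#' @param image matrix (single channel) or H x W x 3 array.
#' @param midline a [extract_midline()] result.
#' @param half_width ribbon half-width in pixels.
#' @return Matrix `(2 * half_width + 1) x m`, or an array with a third
#'   channel dimension for 3-channel input. Column `j` corresponds to arc
#'   position `(j - 1) * midline$step`.
#' @export
straighten <- function(image, midline, half_width = 5) {
  pts <- midline$points
  m <- nrow(pts)
  # tangents by central differences
  tr <- c(pts[2, 1] - pts[1, 1], pts[-1, 1] - pts[-m, 1])
  tc <- c(pts[2, 2] - pts[1, 2], pts[-1, 2] - pts[-m, 2])
  tr2 <- (c(tr[-1], tr[m]) + tr) / 2
  tc2 <- (c(tc[-1], tc[m]) + tc) / 2
  nrm <- sqrt(tr2^2 + tc2^2)
  nrm[nrm == 0] <- 1
  nr <- -tc2 / nrm; nc <- tr2 / nrm
  offs <- seq(-half_width, half_width)
  rgrid <- outer(offs, nr, `*`) + matrix(pts[, 1], length(offs), m, byrow = TRUE)
  cgrid <- outer(offs, nc, `*`) + matrix(pts[, 2], length(offs), m, byrow = TRUE)
  sample_one <- function(ch) {
    v <- bilinear_sample(ch, as.vector(rgrid), as.vector(cgrid))
    if (isTRUE(attr(v, "clamped")))
      warning("midline ribbon exits the image; samples clamped to border")
    matrix(v, length(offs), m)
  }
  if (length(dim(image)) == 3L) {
    out <- array(0, dim = c(length(offs), m, dim(image)[3]))
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- sample_one(image[, , ch])
    out
  } else {
    sample_one(image)
  }
}
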