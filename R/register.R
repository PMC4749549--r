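#' Quality-control spatial footprints
#'
#' Thresholds each footprint at 50% of its maximum weight (pixels below the
#' threshold are set to exactly zero), measures area, effective radius and
#' circularity on the thresholded mask, and discards footprints whose radius
#' falls outside `[radius_min, radius_max]` um or whose circularity is below
#' `circ_min`. Circularity is `4 * pi * A / P^2` with the perimeter estimated
#' from the boundary edge count by the Cauchy-Crofton correction (`P = edges *
#' pi / 4`), clamped to 1.
#'
#' @param patches list of footprint weight matrices (1 um/px, `origin`
#'   attribute as produced by [render_footprints()]).
#' @param radius_min,radius_max admissible effective radius in um.
#' @param circ_min minimum circularity.
#' @param um_per_px micrometer calibration.
#' @return list with `keep` (logical), `qc` (data.frame of area_um2,
#'   radius_um, circularity), and `patches` (thresholded, kept only).
#' @export
footprint_qc <- function(patches, radius_min = 5, radius_max = 14,
                         circ_min = 0.8, um_per_px = 1) {
  n <- length(patches)
  qc <- data.frame(area_um2 = numeric(n), radius_um = numeric(n),
                   circularity = numeric(n))
  thresholded <- vector("list", n)
  for (i in seq_len(n)) {
    w <- patches[[i]]
    thr <- 0.5 * max(w)
    mask <- w >= thr & max(w) > 0
    w[!mask] <- 0
    att <- attributes(patches[[i]])
    attributes(w) <- attributes(patches[[i]])
    thresholded[[i]] <- w
    a_px <- sum(mask)
    if (a_px == 0) {
      qc[i, ] <- c(0, 0, 0)
      next
    }
    area <- a_px * um_per_px^2
    per <- mask_boundary_edges(mask) * um_per_px * pi / 4
    circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
    qc[i, ] <- c(area, sqrt(area / pi), circ)
  }
  keep <- qc$radius_um >= radius_min & qc$radius_um <= radius_max &
    qc$circularity >= circ_min
  list(keep = keep, qc = qc, patches = thresholded[keep])
}

# number of exposed pixel edges of a binary mask (4-connectivity boundary)
mask_boundary_edges <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  inner <- m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  up <- m[1:nrow(mask), 2:(ncol(mask) + 1)]
  dn <- m[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)]
  lf <- m[2:(nrow(mask) + 1), 1:ncol(mask)]
  rt <- m[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  sum(inner & !up) + sum(inner & !dn) + sum(inner & !lf) + sum(inner & !rt)
}

#' Align session centroid maps to a reference session
#'
#' Estimates a rigid transform (rotation + translation) per session that
#' brings its centroid projection into the reference session's coordinate
#' frame. The projection cross-correlation is maximized sparsely: for each
#' candidate rotation, displacement vectors between all cross-session
#' centroid pairs are accumulated on a coarse grid and the modal displacement
#' gives the candidate translation (equivalent to cross-correlating Gaussian
#' dot projections); the best coarse match is refined by a least-squares
#' rigid (Kabsch) fit on mutually nearest centroid pairs.
#'
#' @param footprints a `footprint_set`.
#' @param reference session key used as the reference frame (default: first).
#' @param angle_range,angle_step rotation search grid in degrees.
#' @param match_radius um radius for the refinement pairing.
#' @return named list per session: `theta` (radians), `shift` (um, length 2);
#'   `apply_rigid()` maps session coordinates into the reference frame.
#' @export
align_session_maps <- function(footprints, reference = NULL,
                               angle_range = 3, angle_step = 0.5,
                               match_radius = 4) {
  keys <- names(footprints$sessions)
  if (length(keys) < 2) stop("need at least two sessions to align")
  if (is.null(reference)) reference <- keys[1]
  ref <- footprints$sessions[[reference]]$centroids
  if (nrow(ref) < 3) stop("degenerate reference map: fewer than 3 cells")
  ctr <- colMeans(ref)
  angles <- seq(-angle_range, angle_range, by = angle_step) * pi / 180

  out <- list()
  for (key in keys) {
    cen <- footprints$sessions[[key]]$centroids
    if (nrow(cen) < 3) stop("degenerate map in session ", key)
    if (key == reference) {
      out[[key]] <- list(theta = 0, shift = c(0, 0))
      next
    }
    best <- NULL
    for (th in angles) {
      rot <- rotate_about(cen, th, ctr)
      # candidate translations: modes of the pairwise displacement field on
      # a 2-um grid, each scored by its mutual nearest-neighbor match count
      dx <- outer(ref[, 1], rot[, 1], "-")
      dy <- outer(ref[, 2], rot[, 2], "-")
      ok <- abs(dx) < 25 & abs(dy) < 25
      if (!any(ok)) next
      tab <- sort(table(paste(round(dx[ok] / 2), round(dy[ok] / 2))),
                  decreasing = TRUE)
      for (top in names(tab)[seq_len(min(3, length(tab)))] ) {
        sh <- as.numeric(strsplit(top, " ")[[1]]) * 2
        shifted <- sweep(rot, 2, sh, "+")
        score <- nrow(nearest_pairs(shifted, ref, match_radius))
        if (is.null(best) || score > best$score)
          best <- list(theta = th, shift = sh, score = score)
      }
    }
    # refine with iterated rigid least-squares fits on mutual NN pairs
    fit <- list(theta = best$theta, shift = best$shift, ctr = ctr)
    for (it in 1:2) {
      rough <- apply_rigid(cen, fit)
      nn <- nearest_pairs(rough, ref, match_radius)
      if (nrow(nn) < 3) break
      fit <- kabsch2d(cen[nn[, 1], , drop = FALSE],
                      ref[nn[, 2], , drop = FALSE], ctr)
    }
    out[[key]] <- fit
  }
  out
}

rotate_about <- function(xy, theta, ctr) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(sweep(xy, 2, ctr) %*% t(R), 2, ctr, "+")
}

#' Apply a rigid transform from [align_session_maps()]
#' @param xy n x 2 matrix of um coordinates.
#' @param transform list with `theta` and `shift`.
#' @param ctr rotation center (defaults to attribute stored in the transform,
#'   else the origin used at fit time must be supplied).
#' @export
apply_rigid <- function(xy, transform, ctr = transform$ctr) {
  if (is.null(ctr)) ctr <- c(0, 0)
  sweep(rotate_about(xy, transform$theta, ctr), 2, transform$shift, "+")
}

# mutually nearest pairs within radius: columns (idx_a, idx_b)
nearest_pairs <- function(a, b, radius) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(integer(0), 0, 2))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nb <- apply(d2, 1, which.min)
  na_ <- apply(d2, 2, which.min)
  i <- seq_len(nrow(a))
  mutual <- na_[nb[i]] == i & d2[cbind(i, nb[i])] <= radius^2
  cbind(i[mutual], nb[i][mutual])
}

# closed-form 2-D rigid fit of points a onto points b about center ctr
kabsch2d <- function(a, b, ctr) {
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  h <- t(ca) %*% cb
  theta <- atan2(h[1, 2] - h[2, 1], h[1, 1] + h[2, 2])
  rot_a <- rotate_about(a, theta, ctr)
  shift <- colMeans(b) - colMeans(rot_a)
  list(theta = theta, shift = shift, ctr = ctr)
}

#' Register cells across sessions
#'
#' After aligning all sessions to the reference frame, sessions are processed
#' in order; each local cell is compared with the current master list either
#' by footprint spatial correlation (register if `> threshold`, default 0.7)
#' or by centroid distance (register if `< threshold` um, default 5).
#' Candidate pairs are assigned greedily from the best score down (maximal
#' correlation / minimal distance), each master and local cell at most once;
#' unmatched local cells found a new master identity.
#'
#' @param footprints a `footprint_set`.
#' @param method `"correlation"` or `"distance"`.
#' @param threshold score threshold (correlation in (0,1); distance in um).
#' @param transforms optional output of [align_session_maps()]; computed
#'   when missing.
#' @return a registration table data.frame `master_id, session_key, local_id,
#'   score, method` with attribute `n_master`.
#' @export
register_cells <- function(footprints, method = c("correlation", "distance"),
                           threshold = NULL, transforms = NULL) {
  method <- match.arg(method)
  if (is.null(threshold)) threshold <- if (method == "correlation") 0.7 else 5
  if (method == "distance" && threshold <= 0)
    stop("distance threshold must be positive")
  if (method == "correlation" && (threshold <= 0 || threshold >= 1))
    stop("correlation threshold must lie in (0, 1)")
  keys <- names(footprints$sessions)
  if (is.null(transforms)) transforms <- align_session_maps(footprints)

  master_cent <- matrix(numeric(0), 0, 2)  # aligned running-mean centroids
  master_n <- integer(0)
  master_patch <- list()
  rows <- list(); rk <- 0L
  n_master <- 0L

  for (key in keys) {
    ses <- footprints$sessions[[key]]
    nloc <- nrow(ses$centroids)
    if (nloc == 0) next
    cent <- apply_rigid(ses$centroids, transforms[[key]])
    assigned_master <- rep(NA_integer_, nloc)
    if (n_master > 0) {
      d2 <- outer(cent[, 1], master_cent[, 1], "-")^2 +
        outer(cent[, 2], master_cent[, 2], "-")^2
      if (method == "distance") {
        score <- sqrt(d2)
        cand <- which(score < threshold, arr.ind = TRUE)
        ord <- order(score[cand])
      } else {
        score <- matrix(NA_real_, nloc, n_master)
        near <- which(d2 < (4 * footprints$config$footprint_radius)^2,
                      arr.ind = TRUE)
        for (r in seq_len(nrow(near))) {
          i <- near[r, 1]; j <- near[r, 2]
          score[i, j] <- patch_correlation(
            ses$patches[[i]], cent[i, ] - ses$centroids[i, ],
            master_patch[[j]]$w, master_patch[[j]]$offset)
        }
        cand <- which(!is.na(score) & score > threshold, arr.ind = TRUE)
        ord <- order(-score[cand])
      }
      if (length(ord) > 0) {
        cand <- cand[ord, , drop = FALSE]
        used_m <- logical(n_master); used_l <- logical(nloc)
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (used_l[i] || used_m[j]) next
          used_l[i] <- TRUE; used_m[j] <- TRUE
          assigned_master[i] <- j
          rk <- rk + 1L
          rows[[rk]] <- data.frame(master_id = j, session_key = key,
                                   local_id = i, score = score[i, j],
                                   method = method)
        }
      }
    }
    for (i in which(is.na(assigned_master))) {
      n_master <- n_master + 1L
      assigned_master[i] <- n_master
      master_cent <- rbind(master_cent, cent[i, ])
      master_n <- c(master_n, 0L)
      master_patch[[n_master]] <- list(w = ses$patches[[i]],
                                       offset = cent[i, ] - ses$centroids[i, ])
      rk <- rk + 1L
      rows[[rk]] <- data.frame(master_id = n_master, session_key = key,
                               local_id = i,
                               score = if (method == "correlation") 1 else 0,
                               method = method)
    }
    # running-mean representative centroid per master identity
    for (i in seq_len(nloc)) {
      mid <- assigned_master[i]
      w <- master_n[mid]
      master_cent[mid, ] <- (master_cent[mid, ] * w + cent[i, ]) / (w + 1)
      master_n[mid] <- w + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_master") <- n_master
  out
}

# Pearson correlation of two footprint patches rendered into their union
# bounding box (zeros outside each patch); offsets shift patch origins into
# the aligned frame. Isotropic footprints make rotation negligible here.
patch_correlation <- function(w1, off1, w2, off2) {
  o1 <- attr(w1, "origin") + off1
  o2 <- attr(w2, "origin") + off2
  x0 <- floor(min(o1[1], o2[1])); y0 <- floor(min(o1[2], o2[2]))
  x1 <- ceiling(max(o1[1] + nrow(w1), o2[1] + nrow(w2)))
  y1 <- ceiling(max(o1[2] + ncol(w1), o2[2] + ncol(w2)))
  nx <- x1 - x0 + 1; ny <- y1 - y0 + 1
  a <- matrix(0, nx, ny); b <- matrix(0, nx, ny)
  ix <- round(o1[1]) - x0 + seq_len(nrow(w1))
  iy <- round(o1[2]) - y0 + seq_len(ncol(w1))
  a[ix, iy] <- w1
  ix <- round(o2[1]) - x0 + seq_len(nrow(w2))
  iy <- round(o2[2]) - y0 + seq_len(ncol(w2))
  b[ix, iy] <- w2
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

#' Registration diagnostics
#'
#' Within-session nearest-neighbor footprint correlations and centroid
#' distances (these bound how similar distinct cells can look), and the
#' average number of cross-session registration candidates per cell as a
#' function of the threshold (a flat curve near 1 indicates threshold-
#' insensitive registration).
#'
#' @param footprints a `footprint_set`.
#' @param transforms optional rigid transforms.
#' @param correlation_thresholds sweep for the candidates-per-cell curve.
#' @return list with `within_nn_correlation`, `within_nn_distance`,
#'   `candidates_curve` (data.frame threshold, mean_candidates).
#' @export
registration_quality_stats <- function(footprints, transforms = NULL,
                                       correlation_thresholds =
                                         seq(0.5, 0.85, by = 0.05)) {
  keys <- names(footprints$sessions)
  if (is.null(transforms)) transforms <- align_session_maps(footprints)
  nn_cor <- c(); nn_dist <- c()
  for (key in keys) {
    ses <- footprints$sessions[[key]]
    n <- nrow(ses$centroids)
    if (n < 2) next
    d <- as.matrix(stats::dist(ses$centroids)); diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    nn_dist <- c(nn_dist, d[cbind(seq_len(n), nn)])
    cc <- vapply(seq_len(n), function(i)
      patch_correlation(ses$patches[[i]], c(0, 0),
                        ses$patches[[nn[i]]], c(0, 0)), numeric(1))
    nn_cor <- c(nn_cor, cc)
  }
  # cross-session candidate counts between consecutive session pairs
  counts <- matrix(0, 0, length(correlation_thresholds))
  for (s in seq_len(length(keys) - 1)) {
    a <- footprints$sessions[[keys[s]]]
    b <- footprints$sessions[[keys[s + 1]]]
    if (nrow(a$centroids) == 0 || nrow(b$centroids) == 0) next
    ca <- apply_rigid(a$centroids, transforms[[keys[s]]])
    cb <- apply_rigid(b$centroids, transforms[[keys[s + 1]]])
    d2 <- outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2
    rad <- (4 * footprints$config$footprint_radius)^2
    cors <- matrix(0, nrow(ca), nrow(cb))
    near <- which(d2 < rad, arr.ind = TRUE)
    for (r in seq_len(nrow(near))) {
      i <- near[r, 1]; j <- near[r, 2]
      cors[i, j] <- patch_correlation(
        a$patches[[i]], ca[i, ] - a$centroids[i, ],
        b$patches[[j]], cb[j, ] - b$centroids[j, ])
    }
    # condition on cells with at least one candidate at the loosest
    # threshold, so turnover (cells absent next session) does not dilute
    has_cand <- rowSums(cors > min(correlation_thresholds)) > 0
    if (!any(has_cand)) next
    row <- vapply(correlation_thresholds,
                  function(th) mean(rowSums(cors[has_cand, , drop = FALSE] >
                                              th)), numeric(1))
    counts <- rbind(counts, row)
  }
  list(
    within_nn_correlation = nn_cor,
    within_nn_distance = nn_dist,
    candidates_curve = data.frame(
      threshold = correlation_thresholds,
      mean_candidates = colMeans(counts)
    )
  )
}
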