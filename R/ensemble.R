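#' @importFrom mclust Mclust mclustBIC
NULL

select_atoms_idx <- function(structure, selection = c("all_heavy", "c_alpha")) {
  selection <- match.arg(selection)
  a <- structure$atoms
  if (selection == "c_alpha") which(a$elety == "CA" & !is_water_resid(a$resid))
  else which(a$elesy != "H" & !is_water_resid(a$resid))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid fit of `mobile` onto `reference` over the selected
#' atoms, solved by singular value decomposition with reflection rejection,
#' so the rotation is always proper (det +1).
#'
#' @param mobile,reference `Structure` objects with matching selections.
#' @param selection `"all_heavy"` or `"c_alpha"`.
#' @return An object of class `superposition`: `rotation` (3x3),
#'   `translation` (length 3; the fit maps mobile coordinates `x` to
#'   `x %*% t(rotation) + translation`), `rmsd` (post-fit, Angstrom), and
#'   `xyz`, the full transformed mobile coordinate matrix.
#' @export
superpose <- function(mobile, reference, selection = c("all_heavy", "c_alpha")) {
  selection <- match.arg(selection)
  im <- select_atoms_idx(mobile, selection)
  ir <- select_atoms_idx(reference, selection)
  if (length(im) != length(ir))
    stop("selection mismatch: ", length(im), " vs ", length(ir), " atoms")
  if (length(im) == 0L) stop("empty atom selection")
  P <- coords(mobile$atoms)[im, , drop = FALSE]
  Q <- coords(reference$atoms)[ir, , drop = FALSE]
  fit <- kabsch(P, Q)
  all_xyz <- sweep(coords(mobile$atoms), 2, fit$cm) %*% t(fit$R)
  all_xyz <- sweep(all_xyz, 2, fit$cq, `+`)
  structure(list(rotation = fit$R,
                 translation = as.numeric(fit$cq - fit$R %*% fit$cm),
                 rmsd = fit$rmsd, xyz = all_xyz, selection = selection),
            class = "superposition")
}

# core Kabsch solver on two coordinate matrices
kabsch <- function(P, Q) {
  cm <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cm); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  list(R = R, cm = cm, cq = cq, rmsd = rmsd)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition (%s): rmsd %.4f A\n", x$selection, x$rmsd))
  invisible(x)
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is rigidly superposed onto the reference before the RMSD is
#' taken, mirroring the usual trajectory-analysis convention.
#'
#' @param traj a `Trajectory`.
#' @param reference reference frame index (default 1).
#' @param selection `"all_heavy"` or `"c_alpha"`.
#' @return Numeric vector of RMSD values (Angstrom), one per frame.
#' @export
rmsd_series <- function(traj, reference = 1L,
                        selection = c("all_heavy", "c_alpha")) {
  selection <- match.arg(selection)
  if (length(traj$frames) == 0L) stop("empty trajectory")
  ref <- traj$frames[[reference]]
  vapply(traj$frames, function(f) superpose(f, ref, selection)$rmsd, 0)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto their mean structure (two fit-mean iterations),
#' then each residue's fluctuation about its mean position is computed over
#' the selected atoms.
#'
#' @inheritParams rmsd_series
#' @return data.frame `key`, `chain`, `resno`, `resid`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = c("c_alpha", "all_heavy")) {
  selection <- match.arg(selection, c("c_alpha", "all_heavy"))
  frames <- traj$frames
  if (length(frames) == 1L)
    warning("single-frame trajectory: all fluctuations are zero")
  idx <- select_atoms_idx(frames[[1]], selection)
  if (length(idx) == 0L) stop("empty atom selection")
  xyz <- lapply(frames, function(f) coords(f$atoms)[idx, , drop = FALSE])
  # iterative superposition to the mean structure
  ref <- xyz[[1]]
  for (it in 1:2) {
    fitted <- lapply(xyz, function(x) {
      k <- kabsch(x, ref)
      sweep(sweep(x, 2, k$cm) %*% t(k$R), 2, k$cq, `+`)
    })
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  mean_xyz <- ref
  dev2 <- Reduce(`+`, lapply(fitted, function(x) rowSums((x - mean_xyz)^2))) /
    length(fitted)
  a <- frames[[1]]$atoms[idx, , drop = FALSE]
  keys <- atom_res_keys(a)
  per_res <- vapply(unique(keys), function(k) sqrt(mean(dev2[keys == k])), 0)
  first <- !duplicated(keys)
  data.frame(key = unique(keys), chain = a$chain[first], resno = a$resno[first],
             resid = a$resid[first], rmsf = unname(per_res),
             stringsAsFactors = FALSE)
}

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

backbone_xyz <- function(structure, key, elety) {
  at <- get_atom(structure, key, elety)
  if (nrow(at) != 1L)
    stop("missing backbone atom ", elety, " in residue ", key)
  as.numeric(at[, c("x", "y", "z")])
}

#' Featurize a trajectory for conformational clustering
#'
#' Builds a frames-by-features matrix from backbone phi/psi dihedral angles
#' (encoded as sin/cos pairs, so angle features are bounded in [-1, 1]) and
#' all pairwise C-alpha distances among the selected residues.  Dihedrals
#' are emitted only for residues where both phi and psi are defined (i.e.
#' residues with both sequence neighbours present).  Columns are named
#' `phi_sin_<key>`, `phi_cos_<key>`, `psi_sin_<key>`, `psi_cos_<key>` and
#' `dCA_<key1>_<key2>`, in that order.
#'
#' @param traj a `Trajectory`.
#' @param residues residue keys to use (default: all non-water residues).
#' @return Numeric matrix (frames x features) of class `feature_matrix`.
#' @export
featurize <- function(traj, residues = NULL) {
  s1 <- traj$frames[[1]]
  rt <- residue_table(s1)
  rt <- rt[!rt$water, , drop = FALSE]
  if (is.null(residues)) residues <- rt$key
  if (!all(residues %in% rt$key))
    stop("unknown residue key(s): ",
         paste(setdiff(residues, rt$key), collapse = ", "))
  # residues with both neighbours inside the same chain get phi/psi
  dihed <- residues[vapply(residues, function(k) {
    cr <- chain_residues(s1, parse_res_key(k)$chain)
    pos <- match(k, cr$key)
    pos > 1 && pos < nrow(cr)
  }, TRUE)]
  neigh <- lapply(dihed, function(k) {
    cr <- chain_residues(s1, parse_res_key(k)$chain)
    pos <- match(k, cr$key)
    c(prev = cr$key[pos - 1], nxt = cr$key[pos + 1])
  })
  names(neigh) <- dihed
  feat_frame <- function(f) {
    vals <- c()
    for (k in dihed) {
      phi <- torsion_angle(backbone_xyz(f, neigh[[k]]["prev"], "C"),
                           backbone_xyz(f, k, "N"),
                           backbone_xyz(f, k, "CA"),
                           backbone_xyz(f, k, "C"))
      psi <- torsion_angle(backbone_xyz(f, k, "N"),
                           backbone_xyz(f, k, "CA"),
                           backbone_xyz(f, k, "C"),
                           backbone_xyz(f, neigh[[k]]["nxt"], "N"))
      vals <- c(vals, sin(phi), cos(phi), sin(psi), cos(psi))
    }
    if (length(residues) >= 2) {
      ca <- do.call(rbind, lapply(residues, function(k) backbone_xyz(f, k, "CA")))
      d <- cross_dist(ca, ca)
      vals <- c(vals, d[upper.tri(d)])
    }
    vals
  }
  X <- do.call(rbind, lapply(traj$frames, feat_frame))
  cn <- c()
  for (k in dihed)
    cn <- c(cn, paste0(c("phi_sin_", "phi_cos_", "psi_sin_", "psi_cos_"), k))
  if (length(residues) >= 2) {
    pr <- which(upper.tri(diag(length(residues))), arr.ind = TRUE)
    cn <- c(cn, paste0("dCA_", residues[pr[, 1]], "_", residues[pr[, 2]]))
  }
  colnames(X) <- cn
  class(X) <- c("feature_matrix", class(X))
  X
}

mean_silhouette <- function(X, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, dist(X))
  mean(sil[, "sil_width"])
}

#' Select representative conformations by Gaussian-mixture clustering
#'
#' For each candidate number of clusters `k` a full-covariance Gaussian
#' mixture is fitted; the `k` maximizing the mean silhouette width (ties
#' broken toward smaller `k`) is chosen, and each cluster's representative
#' ("hub") is the frame nearest to the cluster mean in the clustering space.
#' Optionally the features are first reduced by principal components.
#'
#' @param features feature matrix (frames x features), e.g. from
#'   [featurize()].
#' @param k_range candidate cluster counts (default 2:10, truncated to the
#'   number of frames minus one).
#' @param reduce logical; reduce dimensionality by PCA before clustering.
#' @param n_components number of principal components when `reduce = TRUE`.
#' @param seed integer seed (clustering initialisation is deterministic; the
#'   seed is fixed for API stability and any downstream randomness).
#' @return An object of class `ensemble_model`: `n_clusters`, `labels`,
#'   `representatives` (frame indices, one per cluster), `silhouette`
#'   (data.frame `k`, `score`), `space` (the clustering input matrix).
#' @export
select_representatives <- function(features, k_range = 2:10, reduce = FALSE,
                                   n_components = 2, seed = 1L) {
  X <- unclass(features)
  n <- nrow(X)
  keep <- apply(X, 2, function(col) stats::sd(col) > 1e-12)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L || n < 3L) {
    warning("degenerate input: all frames identical; single cluster")
    return(structure(list(n_clusters = 1L, labels = rep(1L, n),
                          representatives = 1L,
                          silhouette = data.frame(k = integer(),
                                                  score = numeric()),
                          space = X), class = "ensemble_model"))
  }
  if (reduce) {
    n_components <- min(n_components, ncol(X), n - 1)
    X <- prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(n_components),
                                                    drop = FALSE]
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0L) stop("k_range leaves no feasible cluster count")
  set.seed(seed)
  fits <- list(); scores <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    fit <- tryCatch(
      suppressWarnings(Mclust(X, G = k_range[i],
                              modelNames = c("VVV", "EEE", "EII"),
                              verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    scores[i] <- mean_silhouette(X, fit$classification)
  }
  if (all(is.na(scores))) stop("no Gaussian-mixture fit succeeded")
  best <- which(scores == max(scores, na.rm = TRUE))[1]  # ties: smaller k
  labels <- fits[[best]]$classification
  reps <- vapply(sort(unique(labels)), function(cl) {
    mu <- colMeans(X[labels == cl, , drop = FALSE])
    members <- which(labels == cl)
    members[which.min(rowSums(sweep(X[members, , drop = FALSE], 2, mu)^2))]
  }, 0L)
  structure(list(n_clusters = k_range[best], labels = as.integer(labels),
                 representatives = as.integer(reps),
                 silhouette = data.frame(k = k_range, score = scores),
                 space = X),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Ensemble model:", x$n_clusters, "cluster(s) over",
      length(x$labels), "frames\n")
  if (nrow(x$silhouette))
    cat("  silhouette:",
        paste(sprintf("k=%d %.3f", x$silhouette$k, x$silhouette$score),
              collapse = ", "), "\n")
  cat("  representative frames:", paste(x$representatives, collapse = ", "),
      "\n")
  invisible(x)
}
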