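# Structural comparison over ensembles: least-squares Calpha superposition,
# RMSD, per-residue fluctuation after iterative superposition onto the
# ensemble mean, and TM-score with a fixed residue correspondence. The
# correspondence is fixed because every comparison here is between models of
# the same sequence (or the same protein's experimental structures);
# sequence-independent structural alignment is deliberately out of scope.

#' Residue correspondence between two models
#'
#' Pairs of positions used jointly for superposition and scoring. `"index"`
#' matches 1-based sequence indices (models of the same query); `"resno"`
#' matches author residue numbers by intersection, which is how predicted
#' models are paired with experimental structures that have missing density.
#' `exclude` drops residues (by the matching key) from the correspondence,
#' e.g. to score a transporter without a mobile terminal helix.
#'
#' @param a,b StructureModel.
#' @param by matching key.
#' @param exclude values of the key to omit.
#' @return data.frame `(i, j)` of positions into `a` and `b`; strictly
#'   increasing in both columns.
#' @export
correspondence <- function(a, b, by = c("index", "resno"), exclude = NULL) {
  by <- match.arg(by)
  ka <- if (by == "index") a$residues$index else a$residues$resno
  kb <- if (by == "index") b$residues$index else b$residues$resno
  common <- intersect(ka, kb)
  if (!is.null(exclude)) common <- setdiff(common, exclude)
  common <- sort(common)
  data.frame(i = match(common, ka), j = match(common, kb))
}

# Kabsch: proper rotation R and translation t minimizing ||X R + t - Y||
# (row vectors). det(R) = +1 always; mirror images are *not* matched.
kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1)) {
    stop("degenerate (collinear) coordinates: superposition undefined")
  }
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- cy - as.vector(cx %*% R)
  rmsd <- sqrt(mean(rowSums((sweep(Xc %*% R, 2, cy, `+`) - Y)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Least-squares superposition of one model onto another
#'
#' Kabsch algorithm on the Calpha atoms of the correspondence; the returned
#' transform is the proper rotation (determinant +1) and translation
#' minimizing the Calpha RMSD, applied as `x %*% rotation + translation`.
#'
#' @param mobile,target StructureModel.
#' @param corr data.frame from [correspondence()]; defaults to matching by
#'   sequence index.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom), and `corr`.
#' @export
superpose <- function(mobile, target, corr = NULL) {
  if (is.null(corr)) corr <- correspondence(mobile, target)
  if (nrow(corr) < 3L) stop("need >= 3 correspondence pairs")
  X <- ca_coords(mobile)[corr$i, , drop = FALSE]
  Y <- ca_coords(target)[corr$j, , drop = FALSE]
  fit <- kabsch(X, Y)
  fit$corr <- corr
  fit
}

#' Apply a rigid transform to a model
#' @param model StructureModel.
#' @param rotation 3x3 proper rotation.
#' @param translation length-3 vector.
#' @return transformed StructureModel.
#' @export
transform_model <- function(model, rotation, translation) {
  m <- as.matrix(model$atoms[, c("x", "y", "z")])
  m <- sweep(m %*% rotation, 2, translation, `+`)
  model$atoms[, c("x", "y", "z")] <- m
  model
}

# Iterative superposition of an L x 3 x n coordinate array onto its mean:
# align all to the current mean, recompute, repeat until the mean moves
# < tol (max Calpha displacement) or max_iter. Returns aligned array, mean,
# and iteration count.
iterative_mean_fit <- function(arr, tol = 1e-4, max_iter = 100L) {
  n <- dim(arr)[3]
  ref <- arr[, , 1]
  for (it in seq_len(max_iter)) {
    for (k in seq_len(n)) {
      f <- kabsch(arr[, , k], ref)
      arr[, , k] <- sweep(arr[, , k] %*% f$rotation, 2, f$translation, `+`)
    }
    new_mean <- apply(arr, c(1, 2), mean)
    if (max(abs(new_mean - ref)) < tol && it > 1L) {
      return(list(aligned = arr, mean = new_mean, iterations = it))
    }
    ref <- new_mean
  }
  list(aligned = arr, mean = ref, iterations = max_iter)
}

ensemble_ca_array <- function(models) {
  mats <- lapply(models, ca_coords)
  L <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, integer(1)) == L)) {
    stop("all models must share the full query positions")
  }
  array(unlist(mats), dim = c(L, 3, length(mats)))
}

#' Per-residue root-mean-square fluctuation of an ensemble
#'
#' All models are superposed onto the iteratively refined mean structure;
#' rmsf at position i is the root of the mean squared Calpha deviation from
#' the mean position.
#'
#' @param models list of StructureModel sharing the query positions.
#' @return numeric vector, one non-negative value per residue; the refined
#'   mean coordinates are attached as `attr(, "mean")`.
#' @export
ensemble_rmsf <- function(models) {
  if (length(models) < 2L) stop("rmsf needs >= 2 models")
  fit <- iterative_mean_fit(ensemble_ca_array(models))
  dev2 <- apply(fit$aligned, 3, function(m) rowSums((m - fit$mean)^2))
  out <- sqrt(rowMeans(dev2))
  attr(out, "mean") <- fit$mean
  attr(out, "iterations") <- fit$iterations
  out
}

tm_d0 <- function(L, d0_min = 0.5) {
  if (L <= 21) return(d0_min)
  max(1.24 * (L - 15)^(1 / 3) - 1.8, d0_min)
}

tm_from_fit <- function(X, Y, sel, d0, L_norm) {
  f <- kabsch(X[sel, , drop = FALSE], Y[sel, , drop = FALSE])
  Xr <- sweep(X %*% f$rotation, 2, f$translation, `+`)
  d <- sqrt(rowSums((Xr - Y)^2))
  list(tm = sum(1 / (1 + (d / d0)^2)) / L_norm, d = d)
}

#' TM-score with fixed residue correspondence
#'
#' Length-normalized structural similarity in (0, 1]. With aligned Calpha
#' sets x_i (model) and y_i (reference),
#' `TM = max over superpositions of (1/L_ref) * sum_i 1/(1 + (d_i/d0)^2)`
#' with `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8` (floored at 0.5 Angstrom for
#' short chains). The maximization uses the standard heuristic: initial
#' superpositions seeded from contiguous fragments at several lengths, each
#' refined by iteratively re-superposing on the residue subset within a
#' distance cutoff until the subset is stable; the best score over all
#' seeds is returned. Normalization is by the *reference* length, so the
#' score is asymmetric for chains of different length.
#'
#' @param model,reference StructureModel.
#' @param corr [correspondence()]; defaults to sequence-index matching.
#' @param d0_min floor for d0.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference, corr = NULL, d0_min = 0.5) {
  if (is.null(corr)) corr <- correspondence(model, reference)
  Lali <- nrow(corr)
  if (Lali < 15L) stop("correspondence too short for TM-score (need >= 15)")
  L_norm <- n_residues(reference)
  d0 <- tm_d0(L_norm, d0_min)
  X <- ca_coords(model)[corr$i, , drop = FALSE]
  Y <- ca_coords(reference)[corr$j, , drop = FALSE]
  frag_lengths <- unique(pmax(4L, c(floor(Lali / c(1L, 2L, 4L, 8L)), 15L)))
  best <- 0
  for (fl in frag_lengths) {
    stride <- if (fl <= 15L) 1L else max(1L, floor(fl / 3))
    starts <- unique(c(seq.int(1L, Lali - fl + 1L, by = stride),
                       Lali - fl + 1L))
    for (st in starts) {
      seed_sel <- st:(st + fl - 1L)
      for (d_cut0 in c(max(d0 + 1, 3.5), max(d0 + 2.5, 5), 8)) {
        sel <- seed_sel
        for (iter in 1:50) {
          res <- tryCatch(tm_from_fit(X, Y, sel, d0, L_norm),
                          error = function(e) NULL)
          if (is.null(res)) break
          if (res$tm > best) best <- res$tm
          d_cut <- d_cut0
          repeat {
            new_sel <- which(res$d < d_cut)
            if (length(new_sel) >= 3L) break
            d_cut <- d_cut + 0.5
          }
          if (identical(new_sel, sel)) break
          sel <- new_sel
        }
      }
    }
  }
  best
}

#' Global Calpha RMSD between two models
#'
#' Single Kabsch superposition over the full correspondence (no outlier
#' rejection) -- the conventional "RMSD between the two structures".
#'
#' @param a,b StructureModel.
#' @param corr [correspondence()]; default sequence-index matching.
#' @return RMSD in Angstrom.
#' @export
rmsd_global <- function(a, b, corr = NULL) {
  superpose(a, b, corr)$rmsd
}

#' TM-score landscape of an ensemble against two references
#'
#' One row per model with its TM-score against each reference (normalized
#' by that reference) and, when scores are supplied, the relative quality
#' score `(MP - MP_min)/MP_min`. The reference-vs-reference TM-scores (both
#' normalizations) are attached as `attr(, "ref_tm")` -- the dashed line of
#' the usual landscape plot.
#'
#' @param ensemble [model_ensemble()] or plain list of StructureModel.
#' @param ref_a,ref_b reference StructureModel.
#' @param scores optional data.frame `(model_id, set_id, score)`.
#' @param by correspondence key ("index" for same-query models, "resno"
#'   against experimental structures).
#' @param exclude residues (by key) excluded from scoring.
#' @return data.frame `(model_id, set_id, tm_a, tm_b, relative_mp)`.
#' @export
tm_landscape <- function(ensemble, ref_a, ref_b, scores = NULL,
                         by = "index", exclude = NULL) {
  models <- if (inherits(ensemble, "ModelEnsemble")) ensemble$models else
    ensemble
  set_of <- if (inherits(ensemble, "ModelEnsemble")) ensemble$set_of else
    NULL
  rows <- lapply(models, function(m) {
    data.frame(
      model_id = m$model_id,
      set_id = if (is.null(set_of)) NA_character_ else
        set_of[[m$model_id]],
      tm_a = tm_score(m, ref_a,
                      correspondence(m, ref_a, by = by, exclude = exclude)),
      tm_b = tm_score(m, ref_b,
                      correspondence(m, ref_b, by = by, exclude = exclude)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(scores)) {
    mp <- scores$score[match(out$model_id, scores$model_id)]
    out$relative_mp <- relative_mp(mp, min(scores$score))
  } else {
    out$relative_mp <- NA_real_
  }
  attr(out, "ref_tm") <- c(
    a_vs_b = tm_score(ref_a, ref_b,
                      correspondence(ref_a, ref_b, by = by,
                                     exclude = exclude)),
    b_vs_a = tm_score(ref_b, ref_a,
                      correspondence(ref_b, ref_a, by = by,
                                     exclude = exclude)))
  rownames(out) <- NULL
  out
}
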