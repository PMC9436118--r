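# Quality filtering of model sets by score statistics, coordinate PCA of
# the surviving ensemble, and iterative outlier pruning. Filtering is
# set-level: a mutated MSA either produces a plausible family of models or
# it poisons all of them, so whole sets are kept or discarded.

#' Read / write per-model score tables
#'
#' CSV with columns `model_id,set_id,score` -- one row per model. Any
#' external scorer (MolProbity or otherwise) can feed the pipeline through
#' this table.
#'
#' @param path CSV file.
#' @return data.frame `(model_id, set_id, score)`.
#' @export
read_score_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model_id", "set_id", "score")
  if (!all(need %in% names(tb))) {
    stop("score table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(tb$score))) stop("non-finite scores in ", path)
  tb[, need]
}

#' @rdname read_score_table
#' @param table data.frame `(model_id, set_id, score)`.
#' @export
write_score_table <- function(table, path) {
  utils::write.csv(table[, c("model_id", "set_id", "score")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Set-level quality filter
#'
#' Pools all model scores, takes their median M and a spread S, and
#' discards every set whose mean score exceeds `M + threshold * S`. Lower
#' scores are better (MolProbity convention), so only the high tail is
#' discarded. The default spread is the sample standard deviation of the
#' pooled scores ("one standard deviation above the median of all models");
#' `spread = "sem"` instead uses the standard error of the mean, for the
#' reading of "standard deviation of the mean" as SEM.
#'
#' @param table data.frame `(model_id, set_id, score)`.
#' @param threshold multiples of the spread above the pooled median.
#' @param spread `"sd"` (pooled sample standard deviation, default) or
#'   `"sem"`.
#' @return list with `kept` and `discarded` (character vectors of set ids)
#'   and `stats` (pooled median, spread value, per-set means).
#' @export
filter_sets <- function(table, threshold = 1, spread = c("sd", "sem")) {
  spread <- match.arg(spread)
  if (nrow(table) == 0L) stop("empty score table")
  if (any(!is.finite(table$score))) stop("non-finite scores")
  med <- stats::median(table$score)
  s <- stats::sd(table$score)
  if (is.na(s)) s <- 0  # single model
  if (spread == "sem") s <- s / sqrt(nrow(table))
  set_means <- tapply(table$score, table$set_id, mean)
  cut <- med + threshold * s
  discarded <- names(set_means)[set_means > cut]
  kept <- setdiff(names(set_means), discarded)
  if (length(set_means) == 1L) {
    warning("only one set: the set-level filter cannot discard it")
    kept <- names(set_means); discarded <- character(0)
  }
  list(kept = kept, discarded = discarded,
       stats = list(median = med, spread = s, spread_kind = spread,
                    cutoff = cut,
                    set_means = set_means))
}

#' Relative quality score
#'
#' `(score - min_score) / min_score`: 0 at the best (minimum) score,
#' positive above it. The usual color scale of TM-score landscape plots.
#'
#' @param score numeric vector.
#' @param min_score positive scalar, the campaign's minimum score.
#' @export
relative_mp <- function(score, min_score) {
  stopifnot(length(min_score) == 1L)
  if (!is.finite(min_score) || min_score <= 0) {
    stop("min_score must be > 0")
  }
  (score - min_score) / min_score
}

# van der Waals radii (Angstrom) by element, inferred from atom names
vdw_radius <- function(elety) {
  el <- sub("^[0-9]+", "", toupper(trimws(elety)))
  el <- substr(el, 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Steric-clash proxy score
#'
#' Counts non-bonded heavy-atom pairs whose distance is below the sum of
#' van der Waals radii minus `overlap_threshold`, excluding pairs within
#' the same or sequence-adjacent residues, and scales the count per 1000
#' atoms (the clashscore convention). This is a clash-only proxy for
#' ranking predicted models -- it is NOT MolProbity, whose composite score
#' also weighs Ramachandran and rotamer statistics; use
#' [read_score_table()] to feed real MolProbity scores in.
#'
#' @param model StructureModel.
#' @param overlap_threshold Angstrom of allowed van der Waals overlap.
#' @return clashes per 1000 atoms; raw count in `attr(, "clashes")`.
#' @export
clash_proxy_score <- function(model, overlap_threshold = 0.4) {
  at <- model$atoms
  m <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(m)
  r <- vdw_radius(at$elety)
  d2 <- outer(rowSums(m^2), rowSums(m^2), `+`) - 2 * tcrossprod(m)
  d2[d2 < 0] <- 0
  lim <- outer(r, r, `+`) - overlap_threshold
  close_res <- abs(outer(at$res_index, at$res_index, `-`)) <= 1L
  bad <- (d2 < lim^2) & !close_res & upper.tri(d2)
  count <- sum(bad)
  out <- count / n * 1000
  attr(out, "clashes") <- count
  out
}

#' Coordinate PCA of a model ensemble
#'
#' Models are superposed onto their iteratively refined mean structure;
#' PCA is performed on the flattened Calpha deviation vectors. Reference
#' structures, when given, are superposed onto the same mean and projected
#' onto the components but (by default) do not contribute to the fitted
#' covariance -- experimental structures are placed on the model-derived
#' landscape, not allowed to shape it. Component signs are fixed so each
#' component's largest-magnitude coordinate is positive, making plots
#' reproducible across runs and model orderings.
#'
#' @param models list of StructureModel (or [model_ensemble()]).
#' @param references optional list of StructureModel projected onto the
#'   components.
#' @param fit_references include references in the covariance fit.
#' @return object of class `PCAResult`: `mean_coords` (L x 3),
#'   `eigenvalues` (descending), `components` (3L x k, orthonormal
#'   columns), `projections` (data.frame `model_id`, `PC1`, ...,
#'   `is_reference`).
#' @export
ensemble_pca <- function(models, references = NULL,
                         fit_references = FALSE) {
  if (inherits(models, "ModelEnsemble")) models <- models$models
  if (length(models) + (if (fit_references) length(references) else 0) < 3L) {
    stop("PCA needs >= 3 conformations")
  }
  ids <- vapply(models, function(m) m$model_id, character(1))
  all_models <- c(models, references)
  is_ref <- c(rep(FALSE, length(models)),
              rep(TRUE, length(references)))
  arr <- ensemble_ca_array(all_models)
  fit_idx <- which(!is_ref | fit_references)
  fit <- iterative_mean_fit(arr[, , fit_idx, drop = FALSE])
  # superpose every conformation (refs included) onto the converged mean
  aligned <- arr
  for (k in seq_len(dim(arr)[3])) {
    f <- kabsch(arr[, , k], fit$mean)
    aligned[, , k] <- sweep(arr[, , k] %*% f$rotation, 2, f$translation,
                            `+`)
  }
  L <- dim(arr)[1]
  flat <- t(apply(aligned, 3, as.vector))  # n x 3L
  pc <- stats::prcomp(flat[fit_idx, , drop = FALSE], center = TRUE,
                      scale. = FALSE)
  # sign convention
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  comps <- sweep(pc$rotation, 2, flip, `*`)
  proj <- sweep(flat, 2, pc$center) %*% comps
  k <- ncol(comps)
  projections <- data.frame(
    model_id = c(ids, vapply(references, function(m) m$model_id,
                             character(1))),
    proj, is_reference = is_ref, stringsAsFactors = FALSE)
  names(projections)[2:(k + 1)] <- paste0("PC", seq_len(k))
  structure(list(mean_coords = fit$mean,
                 eigenvalues = pc$sdev^2,
                 components = comps,
                 projections = projections),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  ev <- x$eigenvalues
  share <- if (sum(ev) > 0) round(100 * ev[1:min(2, length(ev))] / sum(ev))
           else rep(0, 2)
  cat("PCAResult:", nrow(x$projections), "conformations,",
      length(ev), "components; PC1", paste0(share[1], "%"),
      if (length(ev) > 1) paste("PC2", paste0(share[2], "%")), "\n")
  invisible(x)
}

#' Iterative outlier pruning in PC1/PC2
#'
#' Automated surrogate for the manual inspect-remove-refit loop: a model is
#' an outlier when its PC1 or PC2 coordinate lies more than `k`
#' MAD-based robust standard deviations from the componentwise median of
#' the model projections. Outliers are removed, the PCA refit, and the rule
#' reapplied until a fixed point. Every removal is logged; an explicit
#' `manual_exclude` list is honored before the automatic rule.
#'
#' @param models list of StructureModel (>= 4).
#' @param references optional references, projected but never pruned.
#' @param k robust-z threshold.
#' @param manual_exclude model_ids removed unconditionally first.
#' @param max_iter safety bound on refit rounds.
#' @return list with `kept` (model_ids), `removed` (data.frame
#'   `model_id, iteration, robust_z`), and `pca` (final PCAResult).
#' @export
prune_outliers <- function(models, references = NULL, k = 3.5,
                           manual_exclude = character(0),
                           max_iter = 20L) {
  if (inherits(models, "ModelEnsemble")) models <- models$models
  stopifnot(length(models) >= 4L)
  ids <- vapply(models, function(m) m$model_id, character(1))
  keep <- !(ids %in% manual_exclude)
  removed <- data.frame(model_id = ids[!keep],
                        iteration = rep(0L, sum(!keep)),
                        robust_z = rep(NA_real_, sum(!keep)),
                        stringsAsFactors = FALSE)
  for (it in seq_len(max_iter)) {
    if (sum(keep) < 3L) stop("outlier pruning would remove nearly all models")
    pca <- ensemble_pca(models[keep], references)
    pr <- pca$projections[!pca$projections$is_reference, , drop = FALSE]
    z <- robust_z2(pr$PC1, if ("PC2" %in% names(pr)) pr$PC2 else NULL)
    out <- which(z > k)
    if (length(out) == 0L) {
      return(list(kept = ids[keep], removed = removed, pca = pca))
    }
    if (length(out) >= sum(keep)) {
      stop("outlier pruning would remove all models")
    }
    removed <- rbind(removed,
                     data.frame(model_id = pr$model_id[out],
                                iteration = it,
                                robust_z = z[out],
                                stringsAsFactors = FALSE))
    keep[match(pr$model_id[out], ids)] <- FALSE
  }
  list(kept = ids[keep], removed = removed,
       pca = ensemble_pca(models[keep], references))
}

# max componentwise robust z over PC1/PC2
robust_z2 <- function(pc1, pc2 = NULL) {
  z1 <- robust_z1(pc1)
  if (is.null(pc2)) return(z1)
  pmax(z1, robust_z1(pc2))
}

robust_z1 <- function(v) {
  s <- stats::mad(v)
  if (s < 1e-12) s <- stats::sd(v)
  if (is.na(s) || s < 1e-12) return(rep(0, length(v)))
  abs(v - stats::median(v)) / s
}
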