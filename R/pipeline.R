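# Campaign orchestration: scan -> mutate -> fold -> collect -> filter ->
# analyze, against a pluggable folding backend. The real backend shells out
# to colabfold_batch; the mock backend folds the hinge toy deterministically
# so the full path is testable without GPU inference.

#' Construct a model ensemble
#'
#' Models grouped by mutation set and run seed, with optional per-model
#' quality scores.
#'
#' @param models named list of StructureModel (names = model_id).
#' @param set_of named character vector model_id -> set_id.
#' @param seed_of named integer vector model_id -> run seed.
#' @param scores optional data.frame `(model_id, set_id, score)`.
#' @return object of class `ModelEnsemble`.
#' @export
model_ensemble <- function(models, set_of, seed_of = NULL, scores = NULL) {
  ids <- vapply(models, function(m) m$model_id, character(1))
  names(models) <- ids
  if (!all(ids %in% names(set_of))) {
    stop("every model must map to a set_id")
  }
  structure(list(models = models, set_of = set_of[ids],
                 seed_of = if (!is.null(seed_of)) seed_of[ids],
                 scores = scores),
            class = "ModelEnsemble")
}

#' @export
print.ModelEnsemble <- function(x, ...) {
  cat("ModelEnsemble:", length(x$models), "models in",
      length(unique(x$set_of)), "set(s)\n")
  invisible(x)
}

#' Subset an ensemble to given sets
#' @param ensemble ModelEnsemble.
#' @param set_ids sets to keep.
#' @export
ensemble_subset <- function(ensemble, set_ids) {
  keep <- names(ensemble$set_of)[ensemble$set_of %in% set_ids]
  model_ensemble(ensemble$models[keep], ensemble$set_of[keep],
                 ensemble$seed_of,
                 if (!is.null(ensemble$scores))
                   ensemble$scores[ensemble$scores$model_id %in% keep, ])
}

#' Mock folding backend over the hinge toy
#'
#' A deterministic test double honoring the folding-backend contract:
#' `fold(msa_path, seed)` returns exactly `models_per_run` models with
#' per-residue pLDDT. It reads the (possibly alanized) query out of the
#' a3m and samples hinge-toy conformations whose mean hinge angle shifts by
#' `effect_angle * f`, where `f` is the fraction of `interface_positions`
#' alanized relative to the baseline query -- so erasing the interface in
#' the MSA measurably and reproducibly changes the output conformations,
#' mimicking what MSA mutagenesis does to a real predictor. Identical
#' `(msa, seed)` input yields byte-identical models.
#'
#' @param spec [hinge_spec()] of the underlying toy.
#' @param interface_positions positions whose alanization drives the shift.
#' @param base_angle mean hinge angle (degrees) for the unmodified MSA.
#' @param effect_angle full angle shift (degrees) at `f = 1`.
#' @param angle_sd within-run angle spread (degrees).
#' @param models_per_run models per fold call.
#' @return backend list with `name`, `models_per_run`, `fold(msa, seed)`.
#' @export
mock_backend <- function(spec, interface_positions, base_angle = 150,
                         effect_angle = -30, angle_sd = 2,
                         models_per_run = 5L) {
  base_query <- hinge_sequence(hinge_length(spec))
  force(interface_positions)
  fold <- function(msa_path, seed) {
    aln <- read_a3m(msa_path)
    q <- strsplit(aln$query, "")[[1]]
    b <- strsplit(base_query, "")[[1]]
    if (length(q) != length(b)) {
      stop("mock backend: query length ", length(q),
           " does not match the hinge toy (", length(b), ")")
    }
    f <- mean(q[interface_positions] == "A" &
                b[interface_positions] != "A")
    # fold determinism: RNG stream derived from (msa content, seed)
    h <- (sum(vapply(q, utf8ToInt, numeric(1)) * seq_along(q)) + 7919 * seed)
    h <- as.integer(h %% 2147483629)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(h)
    angles <- stats::rnorm(models_per_run, base_angle + effect_angle * f,
                           angle_sd)
    lapply(seq_len(models_per_run), function(m) {
      hinge_model(spec, angles[m],
                  model_id = sprintf("seed%d_model%d", seed, m))
    })
  }
  list(name = "mock", models_per_run = as.integer(models_per_run),
       fold = fold)
}

#' ColabFold folding backend
#'
#' Shells out to `colabfold_batch` with templates disabled (the point of
#' the method is to let the predictor find intermediates a template would
#' bias away) and a per-run random seed where the installed ColabFold
#' supports `--random-seed`; when it does not, all runs of a set use
#' ColabFold's own seeding and the manifest records that limitation.
#'
#' @param executable path to `colabfold_batch`.
#' @param models_per_run models per run (`--num-models`).
#' @param extra_args additional command-line arguments.
#' @return backend list with `name`, `models_per_run`, `fold(msa, seed)`.
#' @export
colabfold_backend <- function(executable = Sys.which("colabfold_batch"),
                              models_per_run = 5L,
                              extra_args = character(0)) {
  if (!nzchar(executable) || !file.exists(executable)) {
    stop("colabfold_batch executable not found; supply `executable` or ",
         "use mock_backend()")
  }
  fold <- function(msa_path, seed) {
    out <- tempfile("colabfold_out_")
    dir.create(out)
    args <- c(msa_path, out,
              "--num-models", models_per_run,
              "--random-seed", seed,
              extra_args)
    status <- system2(executable, args)
    if (status != 0) stop("colabfold_batch failed (exit ", status, ")")
    pdbs <- sort(list.files(out, pattern = "\\.pdb$", full.names = TRUE))
    if (length(pdbs) < models_per_run) {
      stop("expected ", models_per_run, " models, found ", length(pdbs))
    }
    lapply(pdbs[seq_len(models_per_run)], read_model)
  }
  list(name = "colabfold", models_per_run = as.integer(models_per_run),
       fold = fold)
}

#' Run a mutagenesis campaign against a folding backend
#'
#' For every entry of the manifest written by [emit_campaign()] (the
#' unmodified MSA included), runs the backend `runs_per_set` times with one
#' seed per run and writes the models under
#' `out_dir/sets/<set_id>/run<k>/model_<m>.pdb`. Completed runs (all model
#' files present) are skipped, so an interrupted campaign resumes without
#' refolding finished sets. A failed run is recorded in the returned log
#' and the campaign continues.
#'
#' @param campaign_dir directory holding `manifest.json` (from
#'   [emit_campaign()]).
#' @param backend [mock_backend()] or [colabfold_backend()].
#' @param seeds one integer per run; default `base_seed + 0:(runs-1)`.
#' @param base_seed used when `seeds` is `NULL`.
#' @return ModelEnsemble of all collected models; the per-run log is
#'   attached as `attr(, "run_log")`.
#' @export
run_campaign <- function(campaign_dir, backend, seeds = NULL,
                         base_seed = 101L) {
  manifest <- read_manifest(campaign_dir)
  runs <- manifest$runs_per_set
  if (is.null(seeds)) seeds <- base_seed + seq_len(runs) - 1L
  if (length(seeds) != runs) {
    stop("need one seed per run (", runs, ")")
  }
  if (backend$models_per_run != manifest$models_per_run) {
    stop("backend produces ", backend$models_per_run,
         " models per run, manifest expects ", manifest$models_per_run)
  }
  models <- list(); set_of <- character(0); seed_of <- integer(0)
  log <- list()
  for (e in manifest$entries) {
    for (k in seq_len(runs)) {
      run_dir <- file.path(campaign_dir, "sets", e$set_id,
                           sprintf("run%d", k))
      paths <- file.path(run_dir,
                         sprintf("model_%d.pdb",
                                 seq_len(manifest$models_per_run)))
      status <- "folded"
      if (!all(file.exists(paths))) {
        dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
        res <- tryCatch(backend$fold(e$msa, seeds[k]),
                        error = function(err) err)
        if (inherits(res, "error")) {
          log[[length(log) + 1L]] <- list(set_id = e$set_id, run = k,
                                          status = "failed",
                                          message = conditionMessage(res))
          next
        }
        for (m in seq_along(res)) write_model(res[[m]], paths[m])
      } else {
        status <- "cached"
      }
      for (m in seq_along(paths)) {
        id <- sprintf("%s_run%d_m%d", e$set_id, k, m)
        mod <- read_model(paths[m], model_id = id)
        models[[id]] <- mod
        set_of[id] <- e$set_id
        seed_of[id] <- seeds[k]
      }
      log[[length(log) + 1L]] <- list(set_id = e$set_id, run = k,
                                      status = status)
    }
  }
  ens <- model_ensemble(models, set_of, seed_of)
  attr(ens, "run_log") <- log
  attr(ens, "manifest") <- manifest
  ens
}

#' Score every model of an ensemble with the clash proxy
#' @param ensemble ModelEnsemble.
#' @param ... passed to [clash_proxy_score()].
#' @return data.frame `(model_id, set_id, score)`.
#' @export
score_ensemble <- function(ensemble, ...) {
  data.frame(
    model_id = names(ensemble$models),
    set_id = unname(ensemble$set_of[names(ensemble$models)]),
    score = vapply(ensemble$models,
                   function(m) as.numeric(clash_proxy_score(m, ...)),
                   numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
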