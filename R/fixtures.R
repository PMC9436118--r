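# Synthetic-data generators. The hinge toy emulates the statistical
# structure the pipeline assumes in real targets: a two-domain protein whose
# conformations vary along one or two rigid hinge modes (open <-> closed
# motions of kinases and transporters), with additive isotropic coordinate
# noise. Geometry is idealized -- helical Calpha traces with backbone
# (N, CA, C, O) plus a Cbeta stub -- which keeps every contact and clash
# oracle exhaustively checkable at O(n^2) while remaining recognisably
# protein-like to distance-based code.

#' Specification of the two-domain hinge toy
#'
#' @param n_per_domain residues per rigid domain.
#' @param linker residues in the inter-domain linker.
#' @param angle_range degrees, length-2; hinge angles are drawn uniformly
#'   from this range. Must lie within (0, 180).
#' @param angle_range2 degrees for the second mode (used when `modes = 2`);
#'   the second rotation is about an axis orthogonal to the first.
#' @param noise_sd Angstrom, isotropic Gaussian noise added to every atom
#'   after rigid hinge placement.
#' @param modes 1 or 2 hinge modes.
#' @return object of class `HingeSpec`.
#' @export
hinge_spec <- function(n_per_domain = 25, linker = 5,
                       angle_range = c(120, 155), angle_range2 = c(10, 30),
                       noise_sd = 0.1, modes = 1) {
  stopifnot(n_per_domain >= 4, linker >= 1, modes %in% c(1, 2),
            length(angle_range) == 2, noise_sd >= 0,
            all(angle_range > 0), all(angle_range < 180),
            diff(angle_range) >= 0)
  structure(list(n_per_domain = n_per_domain, linker = linker,
                 angle_range = angle_range, angle_range2 = angle_range2,
                 noise_sd = noise_sd, modes = modes),
            class = "HingeSpec")
}

hinge_length <- function(spec) 2L * spec$n_per_domain + spec$linker

# cyclic, alanine-free sequence so alanization is always observable
hinge_sequence <- function(n) {
  pool <- strsplit("DEFGHIKLMNPQRSTVWYC", "")[[1]]
  paste(pool[(seq_len(n) - 1L) %% length(pool) + 1L], collapse = "")
}

rot_mat <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Calpha trace: helix A along +z, extended linker, helix B; domain B (and
# the second half of the linker) rotated about the hinge pivot.
hinge_ca_trace <- function(spec, angle1, angle2 = 0) {
  nA <- spec$n_per_domain; nL <- spec$linker; nB <- spec$n_per_domain
  helix <- function(n, z0) {
    i <- seq_len(n) - 1L
    cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
          z0 + 1.5 * i)
  }
  caA <- helix(nA, 0)
  zl <- caA[nA, 3] + 3.8 * seq_len(nL)
  caL <- cbind(rep(0, nL), rep(0, nL), zl)
  caB <- helix(nB, zl[nL] + 3.8)
  ca <- rbind(caA, caL, caB)
  pivot_idx <- nA + ceiling(nL / 2)
  # hinge axis offset laterally so a fully closed domain B packs against
  # domain A at contact distance instead of folding through it
  pivot <- ca[pivot_idx, ] + c(0, 4.4, 0)
  moving <- (pivot_idx + 1L):nrow(ca)
  R <- rot_mat(c(1, 0, 0), angle1)
  if (spec$modes == 2) R <- rot_mat(c(0, 1, 0), angle2) %*% R
  ca[moving, ] <- sweep(sweep(ca[moving, , drop = FALSE], 2, pivot) %*% t(R),
                        2, pivot, `+`)
  ca
}

# backbone + Cbeta stub around a Calpha trace
trace_to_atoms <- function(ca, sequence) {
  n <- nrow(ca)
  nxt <- rbind(ca[-1, , drop = FALSE], ca[n, , drop = FALSE] +
                 (ca[n, ] - ca[n - 1, ]))
  prv <- rbind(ca[1, , drop = FALSE] - (ca[2, ] - ca[1, ]),
               ca[-n, , drop = FALSE])
  t_vec <- nxt - prv
  t_vec <- t_vec / sqrt(rowSums(t_vec^2))
  ref <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
  par <- abs(rowSums(t_vec * ref)) > 0.95
  ref[par, ] <- matrix(rep(c(1, 0, 0), sum(par)), ncol = 3, byrow = TRUE)
  p <- cbind(t_vec[, 2] * ref[, 3] - t_vec[, 3] * ref[, 2],
             t_vec[, 3] * ref[, 1] - t_vec[, 1] * ref[, 3],
             t_vec[, 1] * ref[, 2] - t_vec[, 2] * ref[, 1])
  p <- p / sqrt(rowSums(p^2))
  q <- cbind(t_vec[, 2] * p[, 3] - t_vec[, 3] * p[, 2],
             t_vec[, 3] * p[, 1] - t_vec[, 1] * p[, 3],
             t_vec[, 1] * p[, 2] - t_vec[, 2] * p[, 1])
  aa1 <- strsplit(sequence, "")[[1]]
  res3 <- unname(aa_one_to_three[aa1])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(ca[i, ] - 1.2 * t_vec[i, ] + 0.4 * p[i, ],
                 ca[i, ],
                 ca[i, ] + 1.2 * t_vec[i, ] + 0.4 * q[i, ],
                 ca[i, ] + 1.6 * t_vec[i, ] + 1.4 * q[i, ])
    if (res3[i] != "GLY") {
      nm <- c(nm, "CB")
      xyz <- rbind(xyz, ca[i, ] + 1.5 * p[i, ])
    }
    out[[i]] <- data.frame(res_index = i, resno = i, resid = res3[i],
                           elety = nm, x = xyz[, 1], y = xyz[, 2],
                           z = xyz[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# pLDDT profile: confident domains, low-confidence termini so the
# mean-pLDDT trimming rule has something to trim.
hinge_plddt <- function(n, low_termini = 3L) {
  p <- rep(90, n)
  if (low_termini > 0L) {
    p[seq_len(low_termini)] <- 55
    p[(n - low_termini + 1L):n] <- 55
  }
  p
}

#' Build one hinge-toy model at given hinge angles
#'
#' @param spec [hinge_spec()].
#' @param angle1,angle2 hinge angles (degrees); `angle2` is ignored for
#'   single-mode specs.
#' @param noise_sd overrides the spec's noise level when not `NULL`.
#' @param model_id identifier.
#' @param low_termini residues at each end given low (55) pLDDT; the rest
#'   get 90.
#' @return StructureModel.
#' @export
hinge_model <- function(spec, angle1, angle2 = 0, noise_sd = NULL,
                        model_id = "hinge", low_termini = 3L) {
  if (is.null(noise_sd)) noise_sd <- spec$noise_sd
  n <- hinge_length(spec)
  seqn <- hinge_sequence(n)
  atoms <- trace_to_atoms(hinge_ca_trace(spec, angle1, angle2), seqn)
  if (noise_sd > 0) {
    m <- as.matrix(atoms[, c("x", "y", "z")])
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), 3)
    atoms[, c("x", "y", "z")] <- m
  }
  structure_model(atoms, plddt = hinge_plddt(n, low_termini),
                  model_id = model_id)
}

#' Sample an ensemble of hinge-toy models
#'
#' Hinge angles are drawn uniformly from the spec's range(s); isotropic
#' Gaussian noise is added to every atom. Deterministic under `seed`.
#'
#' @param spec [hinge_spec()].
#' @param n_models number of models.
#' @param seed RNG seed.
#' @param angles optional explicit angle vector (mode 1) overriding the draw.
#' @return list of StructureModel; hinge angles attached as
#'   `attr(, "angles")` (matrix, one column per mode).
#' @export
make_hinge_ensemble <- function(spec, n_models, seed = 1, angles = NULL) {
  stopifnot(n_models >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  a1 <- if (is.null(angles)) {
    stats::runif(n_models, spec$angle_range[1], spec$angle_range[2])
  } else rep_len(angles, n_models)
  a2 <- if (spec$modes == 2) {
    stats::runif(n_models, spec$angle_range2[1], spec$angle_range2[2])
  } else rep(0, n_models)
  models <- lapply(seq_len(n_models), function(i) {
    hinge_model(spec, a1[i], a2[i],
                model_id = sprintf("hinge_%03d", i))
  })
  attr(models, "angles") <- cbind(angle1 = a1, angle2 = a2)
  models
}

#' Generate a synthetic a3m alignment
#'
#' Produces a valid a3m: uppercase gapless query, homologs with `-` at
#' query match columns they lack and lowercase letters for insertions
#' relative to the query. Gap placement is random per column so the
#' gap-skip accounting of [a3m_mutate()] is exercised.
#'
#' @param query_length residues (ignored when `query` given).
#' @param depth total sequences including the query.
#' @param identity probability a homolog retains the query letter at a
#'   non-gap match column.
#' @param gap_fraction probability of `-` at a match column.
#' @param insertion_rate probability of a lowercase insertion (1-3 letters)
#'   after a match column.
#' @param seed RNG seed.
#' @param query explicit query sequence (uppercase, gapless).
#' @return A3MAlignment.
#' @export
make_synthetic_a3m <- function(query_length = 50, depth = 10,
                               identity = 0.6, gap_fraction = 0.1,
                               insertion_rate = 0.05, seed = 1,
                               query = NULL) {
  stopifnot(depth >= 1, identity >= 0, identity <= 1,
            gap_fraction >= 0, gap_fraction < 1,
            insertion_rate >= 0, insertion_rate < 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  aa <- names(aa_one_to_three)
  if (is.null(query)) {
    query <- paste(sample(aa, query_length, replace = TRUE), collapse = "")
  }
  qchars <- strsplit(query, "")[[1]]
  L <- length(qchars)
  headers <- "query"
  seqs <- query
  if (depth > 1) {
    for (k in seq_len(depth - 1L)) {
      out <- character(0)
      for (j in seq_len(L)) {
        if (stats::runif(1) < gap_fraction) {
          out <- c(out, "-")
        } else if (stats::runif(1) < identity) {
          out <- c(out, qchars[j])
        } else {
          out <- c(out, sample(aa, 1))
        }
        if (stats::runif(1) < insertion_rate) {
          out <- c(out, tolower(paste(sample(aa, sample(3, 1),
                                             replace = TRUE),
                                      collapse = "")))
        }
      }
      headers <- c(headers, sprintf("seq_%03d", k))
      seqs <- c(seqs, paste(out, collapse = ""))
    }
  }
  a3m_alignment(headers, seqs)
}

#' Generate a per-model quality-score table
#'
#' Emulates the structure of MolProbity-style composite scores over a model
#' campaign: most scores concentrated in a narrow band (Gaussian around
#' `base_mean`) with designated outlier sets shifted upward, as misfolded
#' sets are in real campaigns.
#'
#' @param sets character vector of set ids.
#' @param n_per_set models per set.
#' @param base_mean,base_sd Gaussian score parameters.
#' @param outlier_sets subset of `sets` shifted by `outlier_shift`.
#' @param outlier_shift additive score shift for outlier sets.
#' @param seed RNG seed.
#' @return data.frame with columns `model_id`, `set_id`, `score`.
#' @export
make_score_table <- function(sets, n_per_set = 15, base_mean = 1.7,
                             base_sd = 0.08, outlier_sets = character(),
                             outlier_shift = 0, seed = 1) {
  stopifnot(all(outlier_sets %in% sets))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rows <- lapply(sets, function(s) {
    mu <- base_mean + if (s %in% outlier_sets) outlier_shift else 0
    data.frame(model_id = sprintf("%s_m%02d", s, seq_len(n_per_set)),
               set_id = s,
               score = stats::rnorm(n_per_set, mu, base_sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
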