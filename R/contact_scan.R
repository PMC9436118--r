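# Contact scanning: pick the confidence-trimmed scannable region, tile it
# with windows, and tabulate which residues each window touches. The
# resulting mutation sets are the unit of the whole campaign.

#' Scan configuration
#'
#' Defaults follow the standard protocol: an 11-residue window, a 4 Angstrom
#' heavy-atom contact cutoff (wide enough to capture polar and ionic
#' interactions including water-mediated ones), and omission of partners
#' within 4 positions of the window in the primary sequence, which protects
#' local secondary structure from being destabilized.
#'
#' @param window_length residues per scan window.
#' @param contact_cutoff Angstrom; minimum heavy-atom distance defining a
#'   contact.
#' @param sequence_exclusion partners closer than this (in sequence) to any
#'   window position are omitted.
#' @param stride window step; defaults to `window_length` (non-overlapping
#'   tiling).
#' @param mutate which pair members enter the mutation set: both (default),
#'   only window residues, or only the partners.
#' @return object of class `ScanConfig`.
#' @export
scan_config <- function(window_length = 11L, contact_cutoff = 4.0,
                        sequence_exclusion = 4L, stride = window_length,
                        mutate = c("both", "window", "partners")) {
  mutate <- match.arg(mutate)
  stopifnot(window_length >= 1, contact_cutoff > 0,
            sequence_exclusion >= 0, stride >= 1)
  structure(list(window_length = as.integer(window_length),
                 contact_cutoff = contact_cutoff,
                 sequence_exclusion = as.integer(sequence_exclusion),
                 stride = as.integer(stride), mutate = mutate),
            class = "ScanConfig")
}

#' Construct a mutation set
#'
#' A named set of 1-based query positions to alanize, with provenance
#' recording whether it came from a scan window or a targeted selection.
#'
#' @param set_id unique identifier within a campaign.
#' @param positions integer vector of 1-based query positions.
#' @param provenance list, e.g. `list(type = "window", start = 1, end = 11)`
#'   or `list(type = "targeted", label = "...")`.
#' @export
mutation_set <- function(set_id, positions, provenance = list(type = "manual")) {
  positions <- sort(unique(as.integer(positions)))
  stopifnot(is.character(set_id), length(set_id) == 1L,
            all(positions >= 1L))
  structure(list(set_id = set_id, positions = positions,
                 provenance = provenance),
            class = "MutationSet")
}

#' @export
print.MutationSet <- function(x, ...) {
  cat("MutationSet", sQuote(x$set_id), "-", length(x$positions),
      "position(s)", if (length(x$positions) == 0L) "[empty]" else "", "\n")
  invisible(x)
}

#' Confidence-trimmed scan region
#'
#' Truncates the N- and C-terminal ends wherever pLDDT falls below the mean
#' over all residues; internal dips below the mean are kept. Equality with
#' the mean counts as confident.
#'
#' @param model StructureModel with pLDDT on every residue.
#' @return integer `c(start, end)`, 1-based inclusive sequence indices.
#' @export
scan_region <- function(model) {
  p <- model$residues$plddt
  if (anyNA(p)) stop("scan_region requires pLDDT on every residue")
  keep <- which(p >= mean(p))
  if (length(keep) == 0L) {
    stop("degenerate model: no residue reaches the mean pLDDT")
  }
  c(start = min(keep), end = max(keep))
}

#' Tile a region with scan windows
#'
#' Non-overlapping tiling at `stride = window_length` by default; when the
#' region length is not a multiple of the stride, the final window is
#' re-anchored at `end - window_length + 1` so every residue of the region
#' is covered. Regions shorter than the window yield a single window over
#' the whole region.
#'
#' @param region `c(start, end)` from [scan_region()].
#' @param config [scan_config()].
#' @return data.frame with columns `start`, `end`, one row per window,
#'   emitted N-to-C.
#' @export
enumerate_windows <- function(region, config = scan_config()) {
  start <- as.integer(region[[1]]); end <- as.integer(region[[2]])
  stopifnot(start >= 1, end >= start)
  w <- config$window_length
  if (end - start + 1L < w) {
    return(data.frame(start = start, end = end))
  }
  starts <- seq.int(start, end - w + 1L, by = config$stride)
  if (starts[length(starts)] != end - w + 1L) {
    starts <- c(starts, end - w + 1L)
  }
  data.frame(start = starts, end = starts + w - 1L)
}

# minimum heavy-atom distance contacts between two residue index sets;
# returns data.frame(i, j, min_dist) for pairs with min_dist <= cutoff
residue_contacts <- function(model, idx_a, idx_b, cutoff) {
  at <- model$atoms
  aa <- at[at$res_index %in% idx_a, , drop = FALSE]
  ab <- at[at$res_index %in% idx_b, , drop = FALSE]
  if (nrow(aa) == 0L || nrow(ab) == 0L) {
    return(data.frame(i = integer(0), j = integer(0),
                      min_dist = numeric(0)))
  }
  ma <- as.matrix(aa[, c("x", "y", "z")])
  mb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), `+`) - 2 * ma %*% t(mb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(i = integer(0), j = integer(0),
                      min_dist = numeric(0)))
  }
  pi_ <- aa$res_index[hit[, 1]]
  pj <- ab$res_index[hit[, 2]]
  key <- paste(pi_, pj)
  dmin <- tapply(sqrt(d2[hit]), key, min)
  ij <- do.call(rbind, strsplit(names(dmin), " "))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
             min_dist = as.numeric(dmin))
}

#' Contact residues of one scan window
#'
#' Tabulates every residue pair (i inside the window, j outside) whose
#' closest heavy atoms lie within the cutoff, omitting partners within
#' `sequence_exclusion` positions of any window position. The returned
#' mutation set is, per `config$mutate`, the union of qualifying window
#' residues and/or their partners. A window with no qualifying contact
#' yields an empty set (flagged via zero positions) which
#' [scan_sets()] excludes from mutagenesis.
#'
#' @param model StructureModel.
#' @param window `c(start, end)` sequence indices.
#' @param config [scan_config()].
#' @param set_id identifier; default derived from the window.
#' @return MutationSet; qualifying pairs attached as `attr(, "pairs")`.
#' @export
window_contacts <- function(model, window, config = scan_config(),
                            set_id = NULL) {
  start <- as.integer(window[[1]]); end <- as.integer(window[[2]])
  n <- n_residues(model)
  if (start < 1L || end > n || start > end) {
    stop("window [", start, ", ", end, "] out of range 1..", n)
  }
  if (is.null(set_id)) set_id <- sprintf("w%03d_%03d", start, end)
  win <- start:end
  excl <- config$sequence_exclusion
  partners_ok <- setdiff(seq_len(n),
                         max(1L, start - excl):min(n, end + excl))
  pairs <- residue_contacts(model, win, partners_ok, config$contact_cutoff)
  positions <- switch(config$mutate,
                      both = union(pairs$i, pairs$j),
                      window = unique(pairs$i),
                      partners = unique(pairs$j))
  ms <- mutation_set(set_id, positions,
                     provenance = list(type = "window", start = start,
                                       end = end))
  attr(ms, "pairs") <- pairs
  ms
}

#' Targeted mutation set from two residue groups
#'
#' Interface mode: every residue of either group participating in an
#' inter-group heavy-atom contact within `cutoff` (e.g. the interface
#' between the N- and C-terminal halves of a pseudo-symmetric transporter).
#' List mode: pass `positions` to accept an explicit residue list verbatim,
#' with no geometry.
#'
#' @param model StructureModel.
#' @param group_a,group_b disjoint integer vectors of sequence indices.
#' @param cutoff Angstrom.
#' @param positions explicit positions (list mode); overrides the groups.
#' @param set_id identifier.
#' @return MutationSet with `provenance$type = "targeted"`.
#' @export
targeted_set <- function(model, group_a = NULL, group_b = NULL, cutoff = 4.0,
                         positions = NULL, set_id = "targeted") {
  if (!is.null(positions)) {
    return(mutation_set(set_id, positions,
                        provenance = list(type = "targeted",
                                          label = "explicit list")))
  }
  stopifnot(!is.null(group_a), !is.null(group_b))
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("targeted groups overlap")
  }
  pairs <- residue_contacts(model, group_a, group_b, cutoff)
  ms <- mutation_set(set_id, union(pairs$i, pairs$j),
                     provenance = list(type = "targeted",
                                       label = "inter-group interface"))
  attr(ms, "pairs") <- pairs
  ms
}

#' Scan a whole model into mutation sets
#'
#' [scan_region()] then [enumerate_windows()] then [window_contacts()] per
#' window. Windows without qualifying contacts are dropped from the result
#' and reported in `attr(, "empty_windows")`.
#'
#' @param model StructureModel with pLDDT.
#' @param config [scan_config()].
#' @return list of non-empty MutationSet.
#' @export
scan_sets <- function(model, config = scan_config()) {
  region <- scan_region(model)
  wins <- enumerate_windows(region, config)
  sets <- lapply(seq_len(nrow(wins)), function(k) {
    window_contacts(model, c(wins$start[k], wins$end[k]), config)
  })
  empty <- vapply(sets, function(s) length(s$positions) == 0L, logical(1))
  out <- sets[!empty]
  attr(out, "region") <- region
  attr(out, "empty_windows") <- wins[empty, , drop = FALSE]
  out
}

#' Serialize mutation sets to JSON
#' @param sets list of MutationSet.
#' @param path output file.
#' @export
write_mutation_sets <- function(sets, path) {
  payload <- lapply(sets, function(s) {
    list(set_id = s$set_id, positions = s$positions,
         provenance = s$provenance)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read mutation sets from JSON
#' @param path file written by [write_mutation_sets()].
#' @return list of MutationSet.
#' @export
read_mutation_sets <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    mutation_set(p$set_id, unlist(p$positions),
                 provenance = p$provenance)
  })
}
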