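# a3m alignments (MMseqs2/ColabFold dialect) and the in-silico alanine
# mutagenesis that is the heart of the method. a3m semantics: the first
# sequence (the query) is uppercase and gapless; in every other sequence a
# '-' marks a gap at a query match column, and lowercase letters are
# insertions relative to the query (a gap in the query). Consequently, for
# every entry, uppercase letters plus dashes add up to exactly the query
# length -- the match-column conservation invariant this module enforces on
# read and preserves under mutation.

#' Construct an A3MAlignment
#'
#' @param headers character vector of sequence headers (without `>`); the
#'   first is the query.
#' @param seqs aligned sequences, same length as `headers`.
#' @param meta verbatim metadata lines (ColabFold pairing `#` lines),
#'   preserved on round-trip.
#' @return object of class `A3MAlignment`.
#' @export
a3m_alignment <- function(headers, seqs, meta = character(0)) {
  stopifnot(length(headers) == length(seqs), length(seqs) >= 1L)
  query <- seqs[[1]]
  if (grepl("[a-z.\\-]", query)) {
    stop("query (first sequence) must be uppercase and gapless; entry ",
         sQuote(headers[[1]]))
  }
  L <- nchar(query)
  for (k in seq_along(seqs)) {
    nm <- a3m_match_count(seqs[[k]])
    if (nm != L) {
      stop("a3m match-column mismatch in entry ", sQuote(headers[[k]]),
           ": uppercase+gap count ", nm, " != query length ", L)
    }
  }
  structure(list(query_id = headers[[1]], query = query,
                 headers = headers, seqs = seqs, meta = meta),
            class = "A3MAlignment")
}

#' @export
print.A3MAlignment <- function(x, ...) {
  cat("A3MAlignment: query", sQuote(x$query_id), "(", nchar(x$query),
      "columns ),", length(x$seqs), "sequences\n")
  invisible(x)
}

# uppercase + '-' count; '.' is an insertion-gap (HH-suite dialect), skipped
a3m_match_count <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sum(chars == "-" | (chars %in% LETTERS))
}

# positions (in the raw string) of the match-state characters of an entry
a3m_match_positions <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  which(chars == "-" | (chars %in% LETTERS))
}

#' Read an a3m alignment
#'
#' Leading `#` lines (ColabFold pairing metadata) are preserved verbatim.
#' Wrapped sequences are concatenated; ColabFold emits one line per
#' sequence, and [write_a3m()] always writes that layout. Every entry is
#' validated against match-column conservation; a violating entry is a hard
#' error naming the entry.
#'
#' @param path a3m file; first sequence must be the query.
#' @return A3MAlignment.
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty a3m file: ", path)
  is_meta <- cumprod(startsWith(lines, "#")) == 1
  meta <- lines[is_meta]
  lines <- lines[!is_meta]
  if (length(lines) == 0L || !startsWith(lines[[1]], ">")) {
    stop("no sequences in ", path)
  }
  hdr_at <- which(startsWith(lines, ">"))
  headers <- sub("^>", "", lines[hdr_at])
  ends <- c(hdr_at[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_at), function(k) {
    if (hdr_at[k] + 1L > ends[k]) stop("entry ", sQuote(headers[k]),
                                       " has no sequence")
    paste(lines[(hdr_at[k] + 1L):ends[k]], collapse = "")
  }, character(1))
  a3m_alignment(headers, seqs, meta = meta)
}

#' Write an a3m alignment
#'
#' One line per sequence, metadata lines first: the ColabFold layout, byte
#' identical on round-trip for files in that layout.
#'
#' @param aln A3MAlignment.
#' @param path output file.
#' @export
write_a3m <- function(aln, path) {
  out <- c(aln$meta,
           as.vector(rbind(paste0(">", aln$headers), unlist(aln$seqs))))
  writeLines(out, path)
  invisible(path)
}

#' Alanize selected query positions across all sequences
#'
#' For every sequence including the query, the match column of each
#' selected position is replaced with `to_residue` -- unless that column
#' holds `-` (the sequence has no residue there), which is left untouched.
#' Lowercase insertion characters have no query equivalent and are never
#' modified; every column outside the selected match columns is byte
#' identical to the input. Alanine erases the co-evolution signal of the
#' selected contacts while being least disruptive to secondary-structure
#' propensity.
#'
#' @param aln A3MAlignment.
#' @param set MutationSet (or bare integer vector of 1-based positions).
#' @param to_residue uppercase 1-letter code; alanine by default.
#' @return mutated A3MAlignment.
#' @export
a3m_mutate <- function(aln, set, to_residue = "A") {
  positions <- if (inherits(set, "MutationSet")) set$positions else
    sort(unique(as.integer(set)))
  stopifnot(length(to_residue) == 1L, nchar(to_residue) == 1L,
            to_residue %in% LETTERS)
  L <- nchar(aln$query)
  if (length(positions) > 0L && max(positions) > L) {
    stop("mutation position ", max(positions), " beyond query length ", L)
  }
  if (length(positions) == 0L) return(aln)
  seqs <- vapply(aln$seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    mc <- which(chars == "-" | (chars %in% LETTERS))
    tgt <- mc[positions]
    tgt <- tgt[chars[tgt] != "-"]
    chars[tgt] <- to_residue
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  a3m_alignment(aln$headers, seqs, meta = aln$meta)
}

#' Number of substitutions [a3m_mutate()] will make per entry
#'
#' `|positions|` minus the number of `-` at the selected match columns of
#' that entry -- the gap-skip accounting.
#'
#' @param aln A3MAlignment.
#' @param positions integer vector of 1-based query positions.
#' @return integer vector, one count per sequence.
#' @export
a3m_substitution_counts <- function(aln, positions) {
  positions <- sort(unique(as.integer(positions)))
  vapply(aln$seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    mc <- which(chars == "-" | (chars %in% LETTERS))
    sum(chars[mc[positions]] != "-")
  }, integer(1), USE.NAMES = FALSE)
}

#' Emit a mutagenesis campaign to disk
#'
#' Writes one mutated a3m per mutation set, the unmodified alignment (which
#' is re-folded the same number of times to give the baseline model set),
#' a FASTA of each mutant query (the mutant sequence is what gets folded),
#' and a JSON manifest of the plan. With the defaults of 3 runs x 5 models,
#' each set is expected to yield 15 models.
#'
#' @param aln A3MAlignment.
#' @param sets list of MutationSet.
#' @param out_dir output directory (created).
#' @param runs_per_set folding runs per MSA.
#' @param models_per_run models per folding run.
#' @param to_residue substitution residue, alanine by default.
#' @return campaign manifest (list), invisibly written to
#'   `manifest.json`.
#' @export
emit_campaign <- function(aln, sets, out_dir, runs_per_set = 3L,
                          models_per_run = 5L, to_residue = "A") {
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate set_id in campaign")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  entries <- list(unmodified = list(
    set_id = "unmodified",
    msa = file.path(out_dir, "unmodified.a3m"),
    fasta = file.path(out_dir, "unmodified.fasta"),
    positions = integer(0)))
  write_a3m(aln, entries$unmodified$msa)
  write_query_fasta(aln$query, aln$query_id, entries$unmodified$fasta)
  for (s in sets) {
    mut <- a3m_mutate(aln, s, to_residue = to_residue)
    e <- list(set_id = s$set_id,
              msa = file.path(out_dir, paste0(s$set_id, ".a3m")),
              fasta = file.path(out_dir, paste0(s$set_id, ".fasta")),
              positions = s$positions,
              provenance = s$provenance)
    write_a3m(mut, e$msa)
    write_query_fasta(mut$query, paste0(aln$query_id, "_", s$set_id),
                      e$fasta)
    entries[[s$set_id]] <- e
  }
  manifest <- list(
    query_id = aln$query_id,
    query_length = nchar(aln$query),
    to_residue = to_residue,
    runs_per_set = as.integer(runs_per_set),
    models_per_run = as.integer(models_per_run),
    n_mutant_sets = length(sets),
    expected_mutant_models =
      length(sets) * as.integer(runs_per_set) * as.integer(models_per_run),
    expected_total_models =
      (length(sets) + 1L) * as.integer(runs_per_set) *
        as.integer(models_per_run),
    entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a campaign manifest
#' @param out_dir campaign directory containing `manifest.json`.
#' @return manifest list as written by [emit_campaign()].
#' @export
read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", out_dir)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$runs_per_set <- as.integer(m$runs_per_set)
  m$models_per_run <- as.integer(m$models_per_run)
  m$entries <- lapply(m$entries, function(e) {
    e$positions <- as.integer(unlist(e$positions))
    e
  })
  m
}
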