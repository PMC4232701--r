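## Subfamily x fragment-region HMM libraries.
##
## Short homology fragments in draft assemblies are classified with profiles
## built from nested regions of a reference alignment (anchored, for GPCR-like
## families, at transmembrane-domain landmarks) and restricted to one
## subfamily's sequences at a time.

#' Define fragment regions on a reference alignment
#'
#' @param name Region names (unique), e.g. `c("TM1-4", "TM4-5", "TM6", "TM6-7")`.
#' @param start_col,end_col 0-based half-open column intervals on the
#'   reference alignment.
#' @return A tibble with columns `name`, `start_col`, `end_col`.
#' @export
fragment_regions <- function(name, start_col, end_col) {
  stopifnot(length(name) == length(start_col),
            length(name) == length(end_col),
            !anyDuplicated(name), all(start_col >= 0),
            all(start_col < end_col))
  tibble(name = as.character(name), start_col = as.integer(start_col),
         end_col = as.integer(end_col))
}

#' Trim an alignment to a fragment region
#'
#' Retains columns `[start_col, end_col)` and drops rows with fewer than
#' `min_residues` non-gap characters inside the region (partial sequences are
#' excluded from profile training).
#'
#' @param aln Alignment tibble (`id`, `seq`, optional `label`).
#' @param region One row of [fragment_regions()] (or a list with `name`,
#'   `start_col`, `end_col`).
#' @param min_residues Minimum non-gap residues a row must have in the region;
#'   default 50% of the region's columns.
#' @return The trimmed alignment tibble.
#' @export
trim_to_region <- function(aln, region,
                           min_residues = ceiling((region$end_col - region$start_col) / 2)) {
  m <- aln_matrix(aln)
  if (region$start_col < 0 || region$end_col > ncol(m)) {
    abort(sprintf("region %s [%d, %d) outside alignment of width %d",
                  region$name, region$start_col, region$end_col, ncol(m)))
  }
  cols <- (region$start_col + 1L):region$end_col
  sub <- m[, cols, drop = FALSE]
  n_res <- rowSums(sub != "-")
  keep <- n_res >= min_residues
  if (!any(keep)) abort(sprintf("all rows dropped in region %s", region$name))
  out <- aln[keep, , drop = FALSE]
  out$seq <- unname(apply(sub[keep, , drop = FALSE], 1, paste, collapse = ""))
  out
}

#' Build a calibrated subfamily x region HMM library
#'
#' One profile is built per (subfamily, region) pair by restricting the
#' labeled reference alignment to that subfamily's rows and trimming to the
#' region's columns. Subfamilies with no surviving rows in a region are
#' recorded as gaps (with a warning) rather than failing. Decoy alignments
#' from unrelated families yield additional profiles used only for reciprocal
#' validation.
#'
#' @param aln Labeled alignment tibble (`id`, `seq`, `label`).
#' @param regions Tibble from [fragment_regions()].
#' @param decoy_alns Named list of unlabeled alignments for decoy families
#'   (optional). Each decoy family is trimmed to the same regions.
#' @param symfrac,tau,weighting,background Passed to [build_profile()].
#' @param min_residues Passed to [trim_to_region()] (default: half the region).
#' @param n_cal,len_cal Calibration settings per profile (`len_cal = NULL`
#'   means `2 * M`).
#' @param seed Base seed; each profile is calibrated with a distinct seed
#'   derived from it, recorded in the library manifest.
#' @return An object of class `hmm_library`: list with `profiles` (named
#'   `subfamily|region`), `decoys`, `regions`, `missing` (tibble of recorded
#'   gaps), and `provenance`.
#' @export
build_library <- function(aln, regions, decoy_alns = NULL,
                          symfrac = 0.5, tau = 5,
                          weighting = "henikoff", background = "canonical",
                          min_residues = NULL, n_cal = 200L, len_cal = NULL,
                          seed = 1L) {
  stopifnot(all(c("id", "seq", "label") %in% names(aln)))
  subfams <- sort(unique(aln$label))
  if (length(subfams) < 2L) abort("need >= 2 subfamily labels")
  profiles <- list()
  missing <- tibble(subfamily = character(), region = character())
  seed_i <- 0L
  build_one <- function(sub_aln, subfam, rg) {
    seed_i <<- seed_i + 1L
    mr <- min_residues %||% ceiling((rg$end_col - rg$start_col) / 2)
    trimmed <- tryCatch(trim_to_region(sub_aln, rg, mr), error = function(e) NULL)
    if (is.null(trimmed)) return(NULL)
    hmm <- tryCatch(
      build_profile(trimmed, name = paste(subfam, rg$name, sep = "|"),
                    subfamily = subfam, region = rg$name,
                    symfrac = symfrac, tau = tau, weighting = weighting,
                    background = background),
      error = function(e) NULL)
    if (is.null(hmm)) return(NULL)
    hmm$train_ids <- trimmed$id
    calibrate(hmm, n_cal = n_cal, len_cal = len_cal %||% (2L * hmm$M),
              seed = seed + seed_i)
  }
  for (s in subfams) {
    sub_aln <- aln[aln$label == s, , drop = FALSE]
    for (j in seq_len(nrow(regions))) {
      rg <- regions[j, ]
      hmm <- build_one(sub_aln, s, rg)
      if (is.null(hmm)) {
        warn(sprintf("no profile for subfamily %s in region %s (no surviving rows)",
                     s, rg$name))
        missing <- dplyr::bind_rows(missing,
                                    tibble(subfamily = s, region = rg$name))
      } else {
        profiles[[hmm$name]] <- hmm
      }
    }
  }
  decoys <- list()
  for (dn in names(decoy_alns %||% list())) {
    for (j in seq_len(nrow(regions))) {
      rg <- regions[j, ]
      hmm <- build_one(decoy_alns[[dn]], paste0("decoy:", dn), rg)
      if (!is.null(hmm)) decoys[[hmm$name]] <- hmm
    }
  }
  structure(list(
    profiles = profiles, decoys = decoys, regions = regions,
    missing = missing,
    provenance = list(
      n_rows = nrow(aln), subfamilies = subfams,
      input_ids = aln$id,
      params = list(symfrac = symfrac, tau = tau, weighting = weighting,
                    background = background, n_cal = n_cal, seed = seed),
      created = format(Sys.time(), tz = "UTC"))
  ), class = "hmm_library")
}

#' @export
print.hmm_library <- function(x, ...) {
  cat(sprintf("<hmm_library> %d profiles (%d subfamilies x %d regions), %d decoys, %d gaps\n",
              length(x$profiles), length(x$provenance$subfamilies),
              nrow(x$regions), length(x$decoys), nrow(x$missing)))
  invisible(x)
}

#' @export
glance.hmm_library <- function(x, ...) {
  tibble(n_profiles = length(x$profiles), n_decoys = length(x$decoys),
         n_subfamilies = length(x$provenance$subfamilies),
         n_regions = nrow(x$regions), n_missing = nrow(x$missing))
}

#' Write a library manifest (regions, profiles, provenance) as JSON
#'
#' @param library An `hmm_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  obj <- list(
    schema = "famscan/hmm_library", schema_version = 1L,
    regions = library$regions,
    profiles = purrr::map(library$profiles, function(h) {
      list(name = h$name, subfamily = h$subfamily, region = h$region,
           M = h$M, n_train = h$n_train, train_ids = h$train_ids,
           calibration = h$calibration)
    }),
    decoys = names(library$decoys),
    missing = library$missing,
    provenance = library$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Truncate sequences after a landmark alignment column
#'
#' Cuts each sequence immediately after its residue aligned at `landmark_col`
#' (gaps skipped), the tail-loss robustness control: by deleting everything
#' beyond the last transmembrane domain from tailed training sequences one can
#' check that the absence of a cytoplasmic C-terminal tail does not by itself
#' drive subfamily classification. Sequences entirely gapped up to the
#' landmark are returned unchanged.
#'
#' @param aln Alignment tibble (`id`, `seq`, optional `label`).
#' @param landmark_col 0-based alignment column of the landmark.
#' @return The alignment tibble with columns after the landmark replaced by
#'   gaps (so residues before the landmark are untouched and the alignment
#'   width is preserved).
#' @export
truncate_at_landmark <- function(aln, landmark_col) {
  m <- aln_matrix(aln)
  if (landmark_col < 0 || landmark_col >= ncol(m)) {
    abort("landmark_col outside alignment")
  }
  ncols <- ncol(m)
  if (landmark_col < ncols - 1L) {
    tail_cols <- (landmark_col + 2L):ncols
    has_res <- rowSums(m[, seq_len(landmark_col + 1L), drop = FALSE] != "-") > 0
    m[has_res, tail_cols] <- "-"
  }
  out <- aln
  out$seq <- unname(apply(m, 1, paste, collapse = ""))
  out
}
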