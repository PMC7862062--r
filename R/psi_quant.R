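#' Read single-end alignments from a SAM or BAM file
#'
#' Thin wrapper around [Rsamtools::scanBam()] returning a tidy alignment
#' table. SAM input is converted to BAM in a temporary directory first.
#' Unmapped records are dropped (with a message when they are all that is
#' present).
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return Tibble with `molecule`, `start`, `end` (1-based inclusive
#'   reference span from the CIGAR) and `strand`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                              indexDestination = FALSE))
  }
  ali <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "cigar", "strand", "flag")))[[1]]
  mapped <- !bitwAnd(ali$flag, 4L)
  if (!any(mapped)) {
    warn(sprintf("'%s' contains no mapped reads", basename(path)))
    return(tibble(molecule = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  tibble(molecule = as.character(ali$rname[mapped]),
         start = ali$pos[mapped],
         end = ali$pos[mapped] + cigar_ref_width(ali$cigar[mapped]) - 1L,
         strand = as.character(ali$strand[mapped]))
}

# reference-space width of a CIGAR string: M/D/N/=/X consume reference,
# I/S/H/P do not
cigar_ref_width <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  map_int(ops, function(m) {
    consume <- m[, 3] %in% c("M", "D", "N", "=", "X")
    as.integer(sum(as.numeric(m[consume, 2])))
  })
}

#' Build a per-position termination profile from alignments
#'
#' For every reference position, counts the reads whose 5'-most aligned
#' base falls there (`n_start`, the RT termination signal) and the reads
#' whose alignment spans it (`n_overlap`; a read starting at a position
#' overlaps it, so `n_start <= n_overlap` everywhere). Reverse-strand
#' alignments are discarded and counted, since the rRNA references are
#' single-stranded.
#'
#' @param alignments A tibble as returned by [read_alignments()] (or the
#'   `reads` element of a [simulate_termination_reads()] result), or a path
#'   to a SAM/BAM file.
#' @param reference_lengths Named integer vector of molecule lengths, or a
#'   [make_reference()] result. Alignment molecule names must all be known.
#' @param sample_id Optional sample label stored on the profile.
#' @return A tibble of class `termination_profile` with columns `molecule`,
#'   `position`, `n_start`, `n_overlap`, and attributes `total_reads`,
#'   `n_reverse_discarded` and `sample_id`.
#' @examples
#' reads <- tibble::tibble(molecule = "M", start = 10L, end = 40L,
#'                         strand = "+")
#' prof <- build_profile(reads, c(M = 100L))
#' prof[prof$position == 10, ]
#' @export
build_profile <- function(alignments, reference_lengths, sample_id = NULL) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments(alignments)
  }
  if (inherits(reference_lengths, "psi_reference")) {
    reference_lengths <- reference_lengths$lengths
  }
  assert_columns(alignments, c("molecule", "start", "end"), "`alignments`")
  unknown <- setdiff(unique(alignments$molecule), names(reference_lengths))
  if (length(unknown)) {
    abort(sprintf("alignments reference unknown molecule(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  n_rev <- 0L
  if ("strand" %in% names(alignments)) {
    rev_sel <- alignments$strand == "-"
    n_rev <- sum(rev_sel)
    if (n_rev > 0) {
      inform(sprintf("discarding %d reverse-strand alignment(s)", n_rev))
      alignments <- alignments[!rev_sel, , drop = FALSE]
    }
  }
  if (nrow(alignments) == 0) {
    warn("no usable alignments; returning an empty (all-zero) profile")
  }
  prof <- map(names(reference_lengths), function(mol) {
    len <- reference_lengths[[mol]]
    sel <- alignments$molecule == mol
    starts <- tabulate(alignments$start[sel], nbins = len)
    cov <- as.integer(IRanges::coverage(
      IRanges::IRanges(alignments$start[sel],
                       pmin(alignments$end[sel], len)),
      width = len))
    tibble(molecule = mol, position = seq_len(len),
           n_start = starts, n_overlap = cov)
  }) |> bind_rows()
  structure(prof, class = c("termination_profile", class(prof)),
            total_reads = nrow(alignments),
            n_reverse_discarded = n_rev,
            sample_id = sample_id)
}

#' Per-site Psi-ratio from a termination profile
#'
#' The Psi-ratio of a site is the number of reads beginning at its position
#' (reverse-transcriptase terminations) divided by the number of reads
#' overlapping it. With `n_overlap` counting starting reads as overlapping
#' (see [build_profile()]), the ratio is a proper fraction in `[0, 1]`
#' interpretable as the termination fraction among site-covering reads.
#' Sites with overlap coverage below `min_coverage` are reported as `NA`.
#'
#' @param profile A [build_profile()] result.
#' @param sites Psi-site table: tibble with `molecule`, `position` and
#'   optionally `site_id` and `guide` (as in `make_reference()$sites`).
#' @param offset Termination offset: the position read out is
#'   `position + offset` (0 = read starts at the site; 1 = one base 3' of
#'   it, the CMC-adduct convention). Must match the assay convention.
#' @param min_coverage Minimum overlap coverage for a ratio to be reported
#'   (default 20; binomial SE < 0.12 at a true ratio of 0.5).
#' @param sample_id Sample label for the output column; defaults to the
#'   profile's label.
#' @return Tibble with one row per site: `site_id`, `molecule`, `position`,
#'   `guide` (if present), `n_start`, `n_overlap`, `psi_ratio`, `sample_id`.
#' @export
psi_ratio <- function(profile, sites, offset = 0, min_coverage = 20,
                      sample_id = NULL) {
  stopifnot(min_coverage >= 1)
  assert_columns(sites, c("molecule", "position"), "`sites`")
  sites <- as_tibble(sites)
  if (!"site_id" %in% names(sites)) {
    sites$site_id <- sprintf("%s:%d", sites$molecule,
                             as.integer(sites$position))
  }
  sample_id <- sample_id %||% attr(profile, "sample_id") %||% "sample"
  lens <- profile |>
    group_by(molecule = .data$molecule) |>
    summarise(len = max(.data$position), .groups = "drop")
  out <- sites |>
    mutate(lookup = as.integer(.data$position + offset)) |>
    left_join(lens, by = "molecule") |>
    left_join(profile, by = c(molecule = "molecule", lookup = "position"))
  outside <- is.na(out$len) | out$lookup < 1 | out$lookup > out$len
  if (any(outside)) {
    warn(sprintf(
      "%d site(s) fall outside the profiled molecules (offset %d) and are reported as missing",
      sum(outside), offset))
    out$n_start[outside] <- NA_integer_
    out$n_overlap[outside] <- NA_integer_
  }
  out |>
    mutate(psi_ratio = if_else(
             !is.na(.data$n_overlap) & .data$n_overlap >= min_coverage,
             .data$n_start / .data$n_overlap, NA_real_),
           sample_id = sample_id) |>
    select(dplyr::any_of(c("site_id", "molecule", "position", "guide")),
           "n_start", "n_overlap", "psi_ratio", "sample_id")
}

#' Stack per-sample Psi-ratio tables into one long matrix
#'
#' @param ... Per-sample tibbles from [psi_ratio()] (or a single list of
#'   them).
#' @return One long tibble (class `psi_ratio_tbl`) with a `sample_id`
#'   column; use [psi_ratio_wide()] for the sites-by-samples matrix layout.
#' @export
psi_ratio_bind <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.data.frame(xs[[1]])) {
    xs <- xs[[1]]
  }
  out <- bind_rows(xs)
  class(out) <- c("psi_ratio_tbl", class(out))
  out
}

#' Sites-by-samples matrix view of a long Psi-ratio table
#'
#' @param psi Long Psi-ratio tibble ([psi_ratio_bind()] output).
#' @return Wide tibble: one row per site, one `psi_ratio` column per sample.
#' @export
psi_ratio_wide <- function(psi) {
  psi |>
    select(dplyr::any_of(c("site_id", "molecule", "position", "guide")),
           "sample_id", "psi_ratio") |>
    pivot_wider(names_from = "sample_id", values_from = "psi_ratio")
}

#' Summed pseudouridylation level over a region of sites
#'
#' Regions of adjacent modified uridines ("hotspots") are summarized per
#' sample by the sum of their site-level Psi-ratios. A sample is flagged
#' incomplete (sum `NA`) when any region site is missing there, so that
#' downstream paired tests only use fully observed samples.
#'
#' @param psi Long Psi-ratio tibble with `molecule`, `position`,
#'   `psi_ratio`, `sample_id`.
#' @param molecule Molecule the region lives on.
#' @param positions Integer vector of site positions (1-based, non-empty);
#'   all must be present in `psi`.
#' @return Tibble with `sample_id`, `region_sum`, `n_sites`, `complete`.
#' @examples
#' # the 18S hotspot at positions 105/109/119 would be
#' # region_sum(psi, "18S", c(105, 109, 119))
#' @export
region_sum <- function(psi, molecule, positions) {
  if (length(positions) == 0) abort("empty region")
  sel <- psi$molecule == molecule & psi$position %in% positions
  have <- unique(psi$position[sel])
  missing_sites <- setdiff(positions, have)
  if (length(missing_sites)) {
    abort(sprintf("region site(s) absent from the Psi-ratio table: %s",
                  paste0(molecule, ":", missing_sites, collapse = ", ")))
  }
  n_region <- length(unique(positions))
  psi[sel, ] |>
    group_by(sample_id = .data$sample_id) |>
    summarise(n_sites = dplyr::n(),
              complete = dplyr::n() == n_region &&
                !any(is.na(.data$psi_ratio)),
              region_sum = if (dplyr::n() == n_region &&
                               !any(is.na(.data$psi_ratio)))
                sum(.data$psi_ratio) else NA_real_,
              .groups = "drop") |>
    select("sample_id", "region_sum", "n_sites", "complete")
}
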