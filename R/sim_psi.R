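#' Build a mock rRNA reference with uridines at the annotated Psi sites
#'
#' Generates one random RNA-like DNA sequence per configured molecule
#' (A/C/G/T, T written at every annotated pseudouridine position, since a
#' Psi is an isomer of uridine) and returns it together with the site
#' annotation table used by the rest of the pipeline.
#'
#' @param config A [sim_psi_config()].
#' @param fasta_path Optional path; when given, the reference is written as
#'   FASTA (via Biostrings) and the path recorded in the result.
#' @return A list of class `psi_reference` with elements
#'   `sequences` (a [Biostrings::DNAStringSet]), `sites` (tibble with
#'   `site_id`, `molecule`, `position`, `stoichiometry`, `guide`) and
#'   `lengths` (named integer vector).
#' @examples
#' cfg <- sim_psi_config(c(M = 300),
#'                       tibble::tibble(molecule = "M", position = 50,
#'                                      stoichiometry = 1, guide = NA))
#' ref <- make_reference(cfg)
#' as.character(Biostrings::subseq(ref$sequences[["M"]], 50, 50))  # "T"
#' @export
make_reference <- function(config, fasta_path = NULL) {
  stopifnot(inherits(config, "sim_psi_config"))
  seqs <- with_seed(derive_seed(config$seed, "reference"), {
    lapply(names(config$molecules), function(m) {
      len <- config$molecules[[m]]
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                     prob = c(0.26, 0.24, 0.24, 0.26))
      base[config$sites$position[config$sites$molecule == m]] <- "T"
      paste(base, collapse = "")
    })
  })
  dss <- Biostrings::DNAStringSet(setNames(unlist(seqs),
                                           names(config$molecules)))
  sites <- config$sites |>
    mutate(site_id = sprintf("%s:%d", .data$molecule,
                             as.integer(.data$position)),
           position = as.integer(.data$position)) |>
    select("site_id", "molecule", "position", "stoichiometry", "guide")
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(dss, fasta_path, width = 70L)
  }
  structure(list(sequences = dss, sites = sites,
                 lengths = config$molecules, fasta_path = fasta_path),
            class = "psi_reference")
}

#' Expected Psi-ratio under the termination model
#'
#' Closed-form expectation of the per-site Psi-ratio produced by the read
#' simulator. Conditional on a cDNA reaching a position, synthesis stops
#' there with probability `1 - (1 - f e)(1 - 1/L)` at a site of
#' stoichiometry `f` with termination efficiency `e` and mean read length
#' `L` (the second factor is the geometric length hazard), and
#' `1 - (1 - b)(1 - 1/L)` at a background position. Because the Psi-ratio is
#' exactly the fraction of position-covering reads that start there, its
#' expectation equals this stop hazard.
#'
#' @param stoichiometry Site stoichiometry `f` in `[0, 1]` (vectorized).
#' @param term_efficiency Termination efficiency `e`.
#' @param background Background stop rate `b` (used when `site = FALSE`).
#' @param mean_read_length Mean read length (geometric length model).
#' @param site If `FALSE`, return the background expectation instead.
#' @return Numeric vector of expected Psi-ratios.
#' @export
expected_psi_ratio <- function(stoichiometry, term_efficiency = 0.8,
                               background = 0.01, mean_read_length = 80,
                               site = TRUE) {
  p_len <- 1 / mean_read_length
  p_evt <- if (site) stoichiometry * term_efficiency else background
  1 - (1 - p_evt) * (1 - p_len)
}

#' Simulate RT-termination reads for one sample
#'
#' Draws reads under the termination model of [sim_psi_config()]: uniform
#' 3' starts, truncated-geometric lengths, stalls at pseudouridine sites
#' with probability `stoichiometry * term_efficiency` and at background
#' positions with probability `background`. Reads are returned pre-mapped
#' (molecule, 1-based start/end, forward strand) and can be written as a
#' coordinate-sorted SAM file with [write_sam()].
#'
#' @param config A [sim_psi_config()]. Per-sample stoichiometries can be
#'   supplied via `stoichiometry`, which overrides the config's column —
#'   this is how tumor/normal or knockdown contrasts are simulated.
#' @param sample_id Sample label; also salts the RNG stream, so different
#'   samples from one config are independent but individually reproducible.
#' @param reference A [make_reference()] result for this config (built on
#'   the fly if omitted; pass it explicitly to avoid rebuilding).
#' @param stoichiometry Optional numeric vector overriding
#'   `config$sites$stoichiometry` (same order as `reference$sites`).
#' @param sam_path Optional path: write the reads as SAM.
#' @return A list of class `psi_sim` with `reads` (tibble: `molecule`,
#'   `start`, `end`, `terminated` — `"site"` or `"other"`),
#'   `truth` (per-site tibble with the stoichiometry used and the
#'   closed-form expected Psi-ratio), `sample_id`, and `sam_path`.
#' @export
simulate_termination_reads <- function(config, sample_id,
                                       reference = NULL,
                                       stoichiometry = NULL,
                                       sam_path = NULL) {
  stopifnot(inherits(config, "sim_psi_config"))
  if (is.null(reference)) reference <- make_reference(config)
  sites <- reference$sites
  if (!is.null(stoichiometry)) {
    stopifnot(length(stoichiometry) == nrow(sites),
              all(stoichiometry >= 0 & stoichiometry <= 1))
    sites$stoichiometry <- stoichiometry
  }
  p_len <- 1 / config$mean_read_length
  fe <- sites$stoichiometry * config$term_efficiency
  b <- config$background
  # per-position stop hazards, length hazard folded in
  haz_site <- 1 - (1 - fe) * (1 - p_len)
  haz_bg <- 1 - (1 - b) * (1 - p_len)

  reads <- with_seed(derive_seed(config$seed,
                                 paste0("reads/", sample_id)), {
    out <- vector("list", length(config$molecules))
    for (i in seq_along(config$molecules)) {
      mol <- names(config$molecules)[i]
      len <- config$molecules[[i]]
      # expected read length under the combined background+length hazard
      # (5' edge truncation included), so realized mean coverage tracks
      # the requested target
      surv <- (1 - b) * (1 - p_len)
      elen <- mean((1 - surv^seq_len(len)) / (1 - surv))
      n_reads <- round(config$coverage * len / elen)
      if (n_reads == 0) {
        out[[i]] <- tibble(molecule = character(), start = integer(),
                           end = integer(), terminated = character())
        next
      }
      idx <- which(sites$molecule == mol)
      # effective stall positions under the offset convention
      ep <- sites$position[idx] + config$offset
      keep <- ep <= len
      ep <- ep[keep]
      hs <- haz_site[idx][keep]
      ord <- order(ep)
      ep <- ep[ord]; hs <- hs[ord]

      t3 <- sample.int(len, n_reads, replace = TRUE)   # 3' start
      # background/length stop: first event among non-site positions
      # walking 5'-wards; geometric over that sub-sequence of positions
      is_site <- logical(len); is_site[ep] <- TRUE
      nonsite_pos <- which(!is_site)
      rank_nonsite <- cumsum(!is_site)                 # C(q)
      g <- rgeom(n_reads, haz_bg)
      bg_idx <- rank_nonsite[t3] - g
      bg_stop <- ifelse(bg_idx >= 1, nonsite_pos[pmax(bg_idx, 1L)], 0L)
      # site stops: independent Bernoulli per crossed site, keep the
      # 3'-most (largest position) stall
      site_stop <- integer(n_reads)
      for (k in rev(seq_along(ep))) {   # ascending kept via rev(desc)
        crossed <- t3 >= ep[k] & site_stop < ep[k]
        if (any(crossed)) {
          hit <- crossed & runif(n_reads) < hs[k]
          site_stop[hit] <- ep[k]
        } else {
          runif(n_reads)  # keep the RNG stream aligned across samples
        }
      }
      start <- pmax(bg_stop, site_stop, 1L)
      # "site" when a Psi stall is the 3'-most stop event; background and
      # geometric length stops are indistinguishable by construction
      terminated <- ifelse(site_stop > 0L & site_stop >= bg_stop,
                           "site", "other")
      out[[i]] <- tibble(molecule = mol, start = as.integer(start),
                         end = as.integer(t3), terminated = terminated)
    }
    bind_rows(out)
  })
  reads <- arrange(reads, match(.data$molecule, names(config$molecules)),
                   .data$start, .data$end)
  if (nrow(reads) == 0) {
    warn(sprintf("sample '%s': zero coverage requested; no reads simulated",
                 sample_id))
  }
  truth <- sites |>
    mutate(expected_ratio = expected_psi_ratio(
      .data$stoichiometry, config$term_efficiency, config$background,
      config$mean_read_length))
  res <- structure(list(reads = reads, truth = truth, sample_id = sample_id,
                        offset = config$offset, sam_path = NULL),
                   class = "psi_sim")
  if (!is.null(sam_path)) {
    write_sam(reads, reference, sam_path, sample_id = sample_id)
    res$sam_path <- sam_path
  }
  res
}

#' Write simulated reads as a coordinate-sorted SAM file
#'
#' Emits standard single-end, forward-strand, fully matched (`<len>M`)
#' records against the simulated reference. The file is plain text and can
#' be converted to BAM with [Rsamtools::asBam()] or `samtools view`.
#'
#' @param reads Tibble with `molecule`, `start`, `end` (1-based inclusive).
#' @param reference A [make_reference()] result (provides lengths and SEQ).
#' @param path Output path (`.sam`).
#' @param sample_id Read-group sample label written to the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path, sample_id = "sample") {
  lens <- reference$lengths
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens),
              sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id))
  reads <- arrange(reads, match(.data$molecule, names(lens)),
                   .data$start, .data$end)
  body <- character(0)
  if (nrow(reads) > 0) {
    seqs <- character(nrow(reads))
    for (mol in unique(reads$molecule)) {
      sel <- reads$molecule == mol
      seqs[sel] <- as.character(Biostrings::extractAt(
        reference$sequences[[mol]],
        IRanges::IRanges(reads$start[sel], reads$end[sel])))
    }
    body <- sprintf("read_%07d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tRG:Z:%s",
                    seq_len(nrow(reads)), reads$molecule, reads$start,
                    reads$end - reads$start + 1L, seqs, sample_id)
  }
  con <- file(path, open = "wb")
  writeLines(c(header, body), con, sep = "\n")
  close(con)
  invisible(path)
}
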