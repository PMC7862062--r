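#' Configuration for the RT-termination (Psi-seq) read simulator
#'
#' Describes a mock rRNA reference together with the pseudouridine sites on
#' it and the stochastic model of reverse-transcriptase termination. The
#' simulator emulates the read-level signature that Psi-seq produces:
#' chemically marked pseudouridines stall the reverse transcriptase, so the
#' 5' starts of reads pile up at modified positions.
#'
#' The generative model (documented in the methods vignette): a cDNA starts
#' at a uniformly placed 3' position and is extended towards the 5' end one
#' nucleotide at a time. At a pseudouridine site extension stops with
#' probability `stoichiometry * term_efficiency`; at any other nucleotide it
#' stops with probability `background`; independently, at every nucleotide
#' synthesis may end for length reasons with probability
#' `1 / mean_read_length` (a truncated-geometric fragment length). The
#' reference 5'-most base of a stalled read equals the site position when
#' `offset = 0`, or one base downstream (`site + 1`) under the CMC-adduct
#' convention `offset = 1`.
#'
#' @param molecules Named integer vector of molecule lengths in nt,
#'   e.g. `c("18S-like" = 500)`. Lengths must be >= 200.
#' @param sites Data frame with columns `molecule`, `position` (1-based),
#'   `stoichiometry` (fraction of molecules modified, in `[0, 1]`) and
#'   `guide` (guiding snoRNA id, `NA` for orphan sites).
#' @param term_efficiency Probability that the RT stalls when it meets a
#'   fully modified site (`e`, in `[0, 1]`). Default 0.8.
#' @param background Per-nucleotide spurious stop probability (`b`). Rare by
#'   construction; capped at 0.05. Default 0.01.
#' @param mean_read_length Mean cDNA length in nt (geometric length model).
#' @param coverage Target mean per-base coverage; the simulator sizes the
#'   read count so realized mean coverage matches this under the combined
#'   stop hazards.
#' @param offset Termination offset convention: 0 (read starts at the site)
#'   or 1 (read starts one base 3' of the site).
#' @param seed Master seed for this configuration.
#' @return An object of class `sim_psi_config`.
#' @examples
#' cfg <- sim_psi_config(
#'   molecules = c("18S-like" = 500),
#'   sites = tibble::tibble(molecule = "18S-like",
#'                          position = c(105, 109, 119),
#'                          stoichiometry = 0.5, guide = "SNORA-demo")
#' )
#' @export
sim_psi_config <- function(molecules,
                           sites,
                           term_efficiency = 0.8,
                           background = 0.01,
                           mean_read_length = 80,
                           coverage = 2000,
                           offset = 0,
                           seed = 1L) {
  sites <- as_tibble(sites)
  assert_columns(sites, c("molecule", "position", "stoichiometry"),
                 "`sites`")
  if (!"guide" %in% names(sites)) sites$guide <- NA_character_
  problems <- character()
  if (is.null(names(molecules)) || any(!nzchar(names(molecules)))) {
    problems <- c(problems, "`molecules` must be a named vector")
  }
  if (any(molecules < 200)) {
    problems <- c(problems, "molecule lengths must be >= 200 nt")
  }
  bad_mol <- setdiff(sites$molecule, names(molecules))
  if (length(bad_mol)) {
    problems <- c(problems, sprintf("sites reference unknown molecule(s): %s",
                                    paste(unique(bad_mol), collapse = ", ")))
  }
  over <- sites$molecule %in% names(molecules) &
    sites$position > molecules[sites$molecule]
  if (any(over)) {
    offending <- sprintf("%s:%d", sites$molecule[over],
                         as.integer(sites$position[over]))
    problems <- c(problems, sprintf(
      "site position(s) exceed molecule length: %s",
      paste(offending, collapse = ", ")))
  }
  if (anyDuplicated(sites[c("molecule", "position")])) {
    problems <- c(problems, "site (molecule, position) pairs must be unique")
  }
  if (any(sites$position < 1)) {
    problems <- c(problems, "site positions must be >= 1")
  }
  if (any(sites$stoichiometry < 0 | sites$stoichiometry > 1)) {
    problems <- c(problems, "stoichiometry must lie in [0, 1]")
  }
  if (term_efficiency < 0 || term_efficiency > 1) {
    problems <- c(problems, "term_efficiency must lie in [0, 1]")
  }
  if (background < 0 || background > 0.05) {
    problems <- c(problems,
                  "background stop rate must lie in [0, 0.05] (rare stops)")
  }
  if (mean_read_length < 2) {
    problems <- c(problems, "mean_read_length must be >= 2 nt")
  }
  if (coverage < 0) problems <- c(problems, "coverage must be >= 0")
  if (!offset %in% c(0, 1)) problems <- c(problems, "offset must be 0 or 1")
  if (length(problems)) {
    abort(c("invalid Psi-seq simulation config:", problems))
  }
  structure(
    list(molecules = setNames(as.integer(molecules), names(molecules)),
         sites = arrange(sites, .data$molecule, .data$position),
         term_efficiency = term_efficiency,
         background = background,
         mean_read_length = mean_read_length,
         coverage = coverage,
         offset = as.integer(offset),
         seed = as.integer(seed)),
    class = "sim_psi_config")
}

#' Configuration for the paired tumor/normal snoRNA count simulator
#'
#' Emulates a snoRNA-seq experiment on matched tumor (T) and normal (N)
#' tissue from the same patients: negative-binomial counts around
#' log-normally distributed baseline abundances, a multiplicative
#' patient effect shared by the two members of each pair, and a designated
#' set of truly up-regulated snoRNAs with a common tumor/normal fold change.
#'
#' Class totals are calibrated so that, in expectation, C/D box snoRNAs
#' absorb `cd_share` and H/ACA box snoRNAs `haca_share` of all mapped reads
#' (defaults mirror the composition typical of lung tissue small-RNA
#' libraries, ~16% and ~4.4%); the remainder of the library is other RNA
#' species, represented only through each sample's total mapped read count.
#'
#' @param n_cd,n_haca Number of C/D box and H/ACA box snoRNAs (defaults 242
#'   and 67, the scale of an annotated human snoRNA capture).
#' @param n_pairs Number of patient tumor/normal pairs (default 7).
#' @param n_up Number of truly up-regulated H/ACA snoRNAs (default 9).
#' @param fold_change True tumor/normal fold change of the up-regulated set
#'   (> 0; default 4).
#' @param dispersion Residual negative-binomial dispersion (1/size; > 0).
#'   This is the technical/sampling component only; biological
#'   between-patient variation is carried by the patient effects below,
#'   which are shared within a pair and therefore cancel in paired tests —
#'   the property that gives matched designs their power.
#' @param pair_effect_sd SD of the global per-patient log-normal effect
#'   (library/tissue scale) shared by both members of a pair.
#' @param gene_patient_sd SD of the gene-by-patient log-normal effect
#'   (per-gene biological level of that patient), also shared within the
#'   pair.
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline snoRNA
#'   abundance before class calibration.
#' @param total_mapped Total mapped reads per sample (library size for
#'   counts-per-million and class-fraction denominators).
#' @param cd_share,haca_share Expected share of total mapped reads per class.
#' @param seed Master seed.
#' @return An object of class `sim_count_config`.
#' @export
sim_count_config <- function(n_cd = 242L,
                             n_haca = 67L,
                             n_pairs = 7L,
                             n_up = 9L,
                             fold_change = 4,
                             dispersion = 0.05,
                             pair_effect_sd = 0.3,
                             gene_patient_sd = 0.3,
                             base_meanlog = 0,
                             base_sdlog = 1.5,
                             total_mapped = 2e6,
                             cd_share = 0.16,
                             haca_share = 0.044,
                             seed = 1L) {
  problems <- character()
  if (n_cd < 2 || n_haca < 2) {
    problems <- c(problems, "need at least 2 snoRNAs per class")
  }
  if (n_pairs < 3) {
    problems <- c(problems, "need >= 3 sample pairs for paired testing")
  }
  if (fold_change <= 0) problems <- c(problems, "fold_change must be > 0")
  if (dispersion <= 0) problems <- c(problems, "dispersion must be > 0")
  if (n_up > n_haca) problems <- c(problems, "n_up cannot exceed n_haca")
  if (cd_share + haca_share >= 1) {
    problems <- c(problems, "class shares must sum to < 1")
  }
  if (length(problems)) abort(c("invalid count simulation config:", problems))
  structure(
    list(n_cd = as.integer(n_cd), n_haca = as.integer(n_haca),
         n_pairs = as.integer(n_pairs), n_up = as.integer(n_up),
         fold_change = fold_change, dispersion = dispersion,
         pair_effect_sd = pair_effect_sd,
         gene_patient_sd = gene_patient_sd,
         base_meanlog = base_meanlog, base_sdlog = base_sdlog,
         total_mapped = total_mapped,
         cd_share = cd_share, haca_share = haca_share,
         seed = as.integer(seed)),
    class = "sim_count_config")
}

#' Configuration for the pooled CRISPR screen count simulator
#'
#' Emulates a dropout/enrichment screen: each target carries 2-6 guide RNAs
#' whose knockout confers a per-doubling fitness effect `s`; cells grow
#' exponentially, so a gRNA's relative abundance evolves proportionally to
#' `(1 + s)^doublings`, and sequencing draws a fixed number of reads per
#' sample (multinomial at `depth`). Two replicates share the fitness truth
#' and the day-0 library composition but are sampled independently.
#'
#' @param targets Data frame with columns `target_id`, `n_grnas` (2-6) and
#'   `fitness` (`s`, per-doubling growth effect; `|s| < 1`; negative values
#'   deplete).
#' @param n_nontargeting Number of non-targeting control gRNAs.
#' @param timepoints Days sampled; must include day 0. Default `c(0, 3, 5, 9)`.
#' @param doublings_per_day Population doublings per day (default 1).
#' @param replicates Number of independent replicates (default 2).
#' @param depth Sequencing reads per sample (multinomial total).
#' @param grna_sd Log-normal SD of per-gRNA day-0 representation.
#' @param seed Master seed.
#' @return An object of class `sim_screen_config`.
#' @export
sim_screen_config <- function(targets,
                              n_nontargeting = 50L,
                              timepoints = c(0, 3, 5, 9),
                              doublings_per_day = 1,
                              replicates = 2L,
                              depth = 5e5,
                              grna_sd = 0.25,
                              seed = 1L) {
  targets <- as_tibble(targets)
  assert_columns(targets, c("target_id", "n_grnas", "fitness"), "`targets`")
  problems <- character()
  if (any(targets$n_grnas < 2 | targets$n_grnas > 6)) {
    problems <- c(problems, "each target must carry 2-6 gRNAs")
  }
  if (any(abs(targets$fitness) >= 1)) {
    problems <- c(problems,
                  "|fitness| must be < 1 (growth factor 1 + s must stay > 0)")
  }
  if (anyDuplicated(targets$target_id)) {
    problems <- c(problems, "target ids must be unique")
  }
  if (any(targets$target_id == "nontargeting")) {
    problems <- c(problems,
                  "'nontargeting' is reserved for control gRNAs")
  }
  if (!0 %in% timepoints || length(timepoints) < 2) {
    problems <- c(problems, "timepoints must include day 0 and one later day")
  }
  if (depth <= 0) problems <- c(problems, "depth must be > 0")
  if (replicates < 1) problems <- c(problems, "need >= 1 replicate")
  if (length(problems)) abort(c("invalid screen simulation config:", problems))
  structure(
    list(targets = targets,
         n_nontargeting = as.integer(n_nontargeting),
         timepoints = sort(unique(as.numeric(timepoints))),
         doublings_per_day = doublings_per_day,
         replicates = as.integer(replicates),
         depth = depth, grna_sd = grna_sd,
         seed = as.integer(seed)),
    class = "sim_screen_config")
}

#' @export
print.sim_psi_config <- function(x, ...) {
  cat("<sim_psi_config>\n")
  cat("  molecules:", paste(sprintf("%s (%d nt)", names(x$molecules),
                                    x$molecules), collapse = ", "), "\n")
  cat(sprintf("  %d Psi sites | e=%.2f b=%.3f len=%.0f cov=%.0fx offset=%d seed=%d\n",
              nrow(x$sites), x$term_efficiency, x$background,
              x$mean_read_length, x$coverage, x$offset, x$seed))
  invisible(x)
}

#' @export
print.sim_count_config <- function(x, ...) {
  cat("<sim_count_config>\n")
  cat(sprintf("  %d C/D + %d H/ACA snoRNAs, %d pairs, %d up at FC %.1f, seed=%d\n",
              x$n_cd, x$n_haca, x$n_pairs, x$n_up, x$fold_change, x$seed))
  invisible(x)
}

#' @export
print.sim_screen_config <- function(x, ...) {
  cat("<sim_screen_config>\n")
  cat(sprintf("  %d targets (%d gRNAs) + %d nontargeting | days %s x %d reps, depth %.0f, seed=%d\n",
              nrow(x$targets), sum(x$targets$n_grnas), x$n_nontargeting,
              paste(x$timepoints, collapse = "/"), x$replicates, x$depth,
              x$seed))
  invisible(x)
}
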