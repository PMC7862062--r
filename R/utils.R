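#' Derive a labeled child seed from a master seed
#'
#' All stochastic stages draw their RNG state from a child seed obtained by
#' hashing a fixed stage label together with the master seed. Adding a new
#' generator therefore never perturbs the random stream of an existing one,
#' and a single `seed` argument reproduces a whole pipeline run.
#'
#' @param seed Master seed (single non-negative integer).
#' @param label Character label of the consuming stage, e.g. `"sim_psi/T1"`.
#' @return A single integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' derive_seed(1L, "sim_psi/sampleA")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- fnv1a32(paste0(format(seed, scientific = FALSE), "\x1f", label))
  # keep strictly below 2^31 - 1 so set.seed() accepts it on all platforms
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash, done in double precision (exact: all intermediates
# stay below 2^53 because we reduce mod 2^32 after every multiply-in-parts).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    # h * 16777619 mod 2^32, split to avoid >2^53 intermediates
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # base bitwXor works on 32-bit signed ints; keep everything unsigned
  r <- bitwXor(as.integer(a %% 2147483648), as.integer(b %% 2147483648))
  r <- as.numeric(r)
  if (r < 0) r <- r + 4294967296
  if (a >= 2147483648) r <- (r + 2147483648) %% 4294967296
  r
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Write a tibble as TSV with provenance header comments
#'
#' Interchange files carry `#`-prefixed header lines recording the package
#' version, the seed and a content hash of the generating configuration, so
#' any output can be traced back to the exact run that produced it.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param comments Named character vector rendered as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, comments = character()) {
  meta <- c(tool = paste0("snopsi ", as.character(packageVersion("snopsi"))),
            comments)
  lines <- sprintf("# %s: %s", names(meta), unname(meta))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  writeLines(lines, con, sep = "\n")
  close(con)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path File path.
#' @return A tibble; header comments are skipped.
#' @export
read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

# short config fingerprint for provenance headers
config_hash <- function(cfg) {
  sprintf("%08x", as.integer(fnv1a32(paste(deparse(cfg, control = "all"),
                                           collapse = "\n")) %% 2147483648))
}

assert_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}
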