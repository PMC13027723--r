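#' Generate synthetic Harboe absorbance records with known hemolysis level
#'
#' Emits the absorbance table the hemolysis readout consumes: three blank
#' replicates read five times each, sample replicates, and the complete
#' hypotonic-lysis reference, all as (A415, A380, A450) triplets. The sample
#' is constructed so that its blank-corrected Harboe value equals
#' `hb_level` times the blank-corrected Harboe value of the lysis reference,
#' before noise.
#'
#' @param hb_level Planted fraction of full lysis (0 = blank, 1 = lysis
#'   reference).
#' @param blank_sd Read-to-read absorbance noise sd applied to every read.
#' @param seed Integer seed.
#' @param n_blank_replicates,n_reads Blank replication scheme (3 x 5 in the
#'   reference protocol).
#' @param blank_true Length-3 true blank optical densities (A415, A380, A450).
#' @param lysis_delta Length-3 blank-corrected absorbances of the 100% lysis
#'   reference.
#' @return data.frame with columns role ("blank", "sample",
#'   "lysis_reference"), replicate, read, A415, A380, A450.
#' @export
generate_absorbance <- function(hb_level, blank_sd = 0.005, seed = 1L,
                                n_blank_replicates = 3L, n_reads = 5L,
                                blank_true = c(0.05, 0.04, 0.03),
                                lysis_delta = c(1.0, 0.25, 0.15)) {
  stopifnot(hb_level >= 0, blank_sd >= 0, n_blank_replicates >= 1,
            n_reads >= 1, length(blank_true) == 3L, length(lysis_delta) == 3L)
  with_gen_seed(seed, {
    noise <- function() if (blank_sd > 0) stats::rnorm(3L, sd = blank_sd) else c(0, 0, 0)
    rows <- list()
    for (rep_ in seq_len(n_blank_replicates)) {
      for (rd in seq_len(n_reads)) {
        a <- blank_true + noise()
        rows[[length(rows) + 1L]] <- data.frame(
          role = "blank", replicate = rep_, read = rd,
          A415 = a[1L], A380 = a[2L], A450 = a[3L])
      }
    }
    for (rep_ in seq_len(3L)) {
      a <- blank_true + hb_level * lysis_delta + noise()
      rows[[length(rows) + 1L]] <- data.frame(
        role = "sample", replicate = rep_, read = 1L,
        A415 = a[1L], A380 = a[2L], A450 = a[3L])
      b <- blank_true + lysis_delta + noise()
      rows[[length(rows) + 1L]] <- data.frame(
        role = "lysis_reference", replicate = rep_, read = 1L,
        A415 = b[1L], A380 = b[2L], A450 = b[3L])
    }
    do.call(rbind, rows)
  })
}
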