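## Fixed biased residue distribution used for the positive class: the
## hydrophobic residues (the hydrophobicity partition's third class,
## C L V I M F W) get weight 3, all others weight 1. Mixing this with the
## uniform baseline at weight delta shifts the positive class's residue
## emission by a tunable amount.
synth_distributions <- function() {
  baseline <- rep(1 / 20, 20)
  names(baseline) <- AA20
  w <- rep(1, 20)
  names(w) <- AA20
  w[c("C", "L", "V", "I", "M", "F", "W")] <- 3
  list(baseline = baseline, biased = w / sum(w))
}

#' Generate a seeded synthetic two-class protein dataset
#'
#' Emulates a two-class sequence benchmark with tunable separation, so the
#' full encode/train/evaluate pipeline is testable without external data.
#' Negatives are drawn i.i.d. from a uniform baseline over the 20 standard
#' residues; positives from the mixture
#' `(1 - delta) * baseline + delta * biased`, where the fixed biased
#' distribution up-weights the hydrophobic residues (C, L, V, I, M, F, W)
#' threefold. `delta = 0` makes the classes statistically
#' indistinguishable; `delta = 1` draws positives purely from the biased
#' distribution. Optionally a short motif overwrites a random stretch of
#' each positive (lengths are preserved). Sequence lengths are uniform on
#' `length_range`; generation is fully deterministic per seed.
#'
#' @param n_pos,n_neg Number of positive (MHC-like) and negative sequences.
#' @param length_range Integer `c(min, max)` sequence lengths; the default
#'   minimum of 61 keeps every sequence encodable under the default
#'   [encoder_config()] (lambda = 30).
#' @param delta Class-separation mixing weight in `[0, 1]`.
#' @param motif Optional residue string written into each positive at a
#'   random position (replacing residues).
#' @param id_prefix Optional string prepended to every sequence ID, so
#'   independently generated datasets (e.g. a train/test pair) have
#'   disjoint IDs.
#' @param seed Integer seed.
#' @return A labeled tibble (`id`, `residues`, `label`) with positives
#'   first; IDs encode class and index (`pos_0001`, `neg_0001`, ...).
#' @export
#' @examples
#' ds <- generate_synthetic(n_pos = 5, n_neg = 5, delta = 0.8, seed = 1)
#' ds$id
generate_synthetic <- function(n_pos = 100, n_neg = 100,
                               length_range = c(61, 300), delta = 0.5,
                               motif = NULL, seed = 1, id_prefix = "") {
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2)
  length_range <- as.integer(length_range)
  if (length_range[1] < 1 || length_range[1] > length_range[2]) {
    abort("length_range must satisfy 1 <= min <= max")
  }
  if (delta < 0 || delta > 1) {
    abort("delta must be in [0, 1]")
  }
  if (!is.null(motif)) {
    motif <- sanitize_residues(motif, "reject")
    if (nchar(motif) > length_range[1]) {
      abort("motif longer than the minimum sequence length")
    }
  }
  dists <- synth_distributions()
  p_pos <- (1 - delta) * dists$baseline + delta * dists$biased

  draw <- function(n, probs, prefix) {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    res <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    tibble(id = sprintf("%s%s_%04d", id_prefix, prefix, seq_len(n)), residues = res)
  }

  withr::with_seed(seed, {
    pos <- draw(n_pos, p_pos, "pos")
    if (!is.null(motif)) {
      ml <- nchar(motif)
      pos$residues <- vapply(pos$residues, function(s) {
        at <- sample.int(nchar(s) - ml + 1L, 1)
        paste0(substr(s, 1, at - 1L), motif, substr(s, at + ml, nchar(s)))
      }, character(1), USE.NAMES = FALSE)
    }
    neg <- draw(n_neg, dists$baseline, "neg")
  })

  dplyr::bind_rows(
    dplyr::mutate(pos, label = 1L),
    dplyr::mutate(neg, label = 0L)
  )
}

#' Write a synthetic dataset as FASTA pair plus manifest
#'
#' Writes `pos.fasta` and `neg.fasta` under `dir`, and a `manifest.json`
#' recording the generator settings.
#'
#' @param data A labeled tibble from [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @param spec Optional named list of generator settings echoed into the
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(data, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(data[data$label == 1L, ], file.path(dir, "pos.fasta"))
  write_fasta(data[data$label == 0L, ], file.path(dir, "neg.fasta"))
  manifest <- list(
    n_pos = sum(data$label == 1L),
    n_neg = sum(data$label == 0L),
    spec = spec
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
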