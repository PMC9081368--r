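#' Encoder configuration
#'
#' Collects every tunable of the mixed-feature encoder: the pseudo
#' amino-acid composition orders and weights, the k-spacing maxima of the
#' conjoint-triad and group-pair encoders, and which descriptor blocks are
#' enabled. The mixed feature vector is the concatenation of the enabled
#' blocks in the fixed order `d188`, `apaac`, `ksctriad`, `cksaagp`,
#' `paac`; its dimension is fully determined by the configuration (see
#' [config_dimension()]).
#'
#' Defaults follow the conventions of the descriptor literature: lambda =
#' 30 and weight 0.05 for both pseudo-composition variants (Chou's
#' canonical values), k up to 0 for triads and up to 5 for group pairs.
#'
#' @param lambda_apaac Sequence-order depth of the amphiphilic pseudo
#'   composition (>= 1); contributes `2 * lambda_apaac` correlation factors.
#' @param w_apaac Weight of those factors relative to composition, in (0,1).
#' @param lambda_paac Sequence-order depth of the type-1 pseudo composition.
#' @param w_paac Its weight, in (0,1).
#' @param kmax_ksctriad Largest residue spacing of the conjoint-triad
#'   encoder (>= 0); one 343-dimensional block per k in `0..kmax`.
#' @param kmax_cksaagp Largest spacing of the group-pair encoder (>= 0);
#'   one 25-dimensional block per k.
#' @param blocks Ordered subset of
#'   `c("d188", "apaac", "ksctriad", "cksaagp", "paac")`.
#' @param ksctriad_norm Per-k-block normalization of triad counts:
#'   `"minmax"` (the conjoint-triad convention, `(c - min) / max`) or
#'   `"window"` (divide by the number of windows).
#' @return An object of class `encoder_config`.
#' @export
#' @examples
#' cfg <- encoder_config(lambda_apaac = 1, lambda_paac = 1, kmax_cksaagp = 0)
#' config_dimension(cfg)  # 188 + 22 + 343 + 25 + 21
encoder_config <- function(lambda_apaac = 30, w_apaac = 0.05,
                           lambda_paac = 30, w_paac = 0.05,
                           kmax_ksctriad = 0, kmax_cksaagp = 5,
                           blocks = c("d188", "apaac", "ksctriad",
                                      "cksaagp", "paac"),
                           ksctriad_norm = c("minmax", "window")) {
  ksctriad_norm <- match.arg(ksctriad_norm)
  known <- c("d188", "apaac", "ksctriad", "cksaagp", "paac")
  if (length(blocks) == 0 || !all(blocks %in% known)) {
    abort(sprintf("blocks must be a non-empty subset of {%s}",
                  paste(known, collapse = ", ")))
  }
  stopifnot(
    lambda_apaac >= 1, lambda_paac >= 1,
    w_apaac > 0, w_apaac < 1, w_paac > 0, w_paac < 1,
    kmax_ksctriad >= 0, kmax_cksaagp >= 0
  )
  structure(
    list(
      lambda_apaac = as.integer(lambda_apaac), w_apaac = w_apaac,
      lambda_paac = as.integer(lambda_paac), w_paac = w_paac,
      kmax_ksctriad = as.integer(kmax_ksctriad),
      kmax_cksaagp = as.integer(kmax_cksaagp),
      blocks = known[known %in% blocks],
      ksctriad_norm = ksctriad_norm
    ),
    class = "encoder_config"
  )
}

#' Total dimension of the mixed feature vector
#'
#' Closed form: `188 + (20 + 2*lambda_apaac) + 343*(kmax_ksctriad + 1) +
#' 25*(kmax_cksaagp + 1) + (20 + lambda_paac)`, counting only enabled
#' blocks.
#'
#' @param config An [encoder_config()].
#' @return Integer dimension.
#' @export
config_dimension <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  dims <- c(
    d188     = 188L,
    apaac    = 20L + 2L * config$lambda_apaac,
    ksctriad = 343L * (config$kmax_ksctriad + 1L),
    cksaagp  = 25L * (config$kmax_cksaagp + 1L),
    paac     = 20L + config$lambda_paac
  )
  sum(dims[config$blocks])
}

#' Minimum sequence length encodable under a configuration
#'
#' The pseudo-composition blocks need `lambda + 1` residues, the triad
#' block `2*kmax + 3`, the group-pair block `kmax + 2`. Sequences shorter
#' than the maximum over the enabled blocks are rejected at encoding time.
#'
#' @param config An [encoder_config()].
#' @return Integer minimum length.
#' @export
min_sequence_length <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  need <- c(
    d188     = 1L,
    apaac    = config$lambda_apaac + 1L,
    ksctriad = 2L * config$kmax_ksctriad + 3L,
    cksaagp  = config$kmax_cksaagp + 2L,
    paac     = config$lambda_paac + 1L
  )
  max(need[config$blocks])
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("<encoder_config>\n")
  cat("  blocks:   ", paste(x$blocks, collapse = " + "), "\n")
  cat(sprintf("  apaac:     lambda = %d, w = %g\n", x$lambda_apaac, x$w_apaac))
  cat(sprintf("  paac:      lambda = %d, w = %g\n", x$lambda_paac, x$w_paac))
  cat(sprintf("  ksctriad:  kmax = %d (%s)\n", x$kmax_ksctriad, x$ksctriad_norm))
  cat(sprintf("  cksaagp:   kmax = %d\n", x$kmax_cksaagp))
  cat(sprintf("  dimension: %d (min length %d)\n",
              config_dimension(x), min_sequence_length(x)))
  invisible(x)
}
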