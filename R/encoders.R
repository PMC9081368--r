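## Descriptor encoders. Every encoder takes a sanitized residue string and
## returns a named numeric vector; names follow the stable
## `block.subblock.item` schema and are part of the model contract.

check_codes <- function(residues) {
  codes <- aa_codes(residues)
  if (length(codes) == 0) {
    abort("cannot encode an empty sequence")
  }
  if (anyNA(codes)) {
    abort("sequence contains non-standard residues; sanitize it first (see read_fasta)")
  }
  codes
}

#' 188-dimensional composition/transition/distribution descriptor
#'
#' The first 20 components are the amino-acid composition (residue
#' frequencies in alphabetical order, summing to 1). Then, for each of the
#' eight physicochemical properties, 21 components: composition (fraction
#' of residues in each of the property's 3 classes), transition (frequency
#' of adjacent residue pairs crossing each unordered class pair, divided by
#' L - 1), and distribution (for each class, the sequence positions — as a
#' percentage of L — of its first, 25%, 50%, 75% and last occurrence; 0 for
#' an absent class). Total: 20 + 8 x 21 = 188.
#'
#' @param residues A sanitized residue string.
#' @param tables Property tables, see [aa_property_tables()].
#' @return Named numeric vector of length 188.
#' @export
#' @examples
#' v <- encode_188d("ACDEFGHIKLMNPQRSTVWY")
#' sum(v[1:20])  # composition sums to 1
encode_188d <- function(residues, tables = aa_property_tables()) {
  codes <- check_codes(residues)
  L <- length(codes)

  aac <- tabulate(codes, 20) / L
  names(aac) <- paste0("d188.AAC.", AA20)

  per_prop <- lapply(ctd_property_order, function(prop) {
    cls <- unname(tables$ctd[[prop]])[codes]
    comp <- tabulate(cls, 3) / L
    names(comp) <- paste0("d188.", prop, ".comp.", 1:3)

    tran <- numeric(3)
    names(tran) <- paste0("d188.", prop, ".tran.", c("12", "13", "23"))
    if (L > 1) {
      a <- cls[-L]
      b <- cls[-1]
      pairs <- list(c(1, 2), c(1, 3), c(2, 3))
      tran[] <- vapply(pairs, function(p) {
        sum((a == p[1] & b == p[2]) | (a == p[2] & b == p[1])) / (L - 1)
      }, numeric(1))
    }

    dist <- numeric(15)
    qs <- c("first", "p25", "p50", "p75", "p100")
    names(dist) <- paste0("d188.", prop, ".dist.",
                          rep(1:3, each = 5), ".", rep(qs, 3))
    for (cl in 1:3) {
      pos <- which(cls == cl)
      n <- length(pos)
      if (n > 0) {
        idx <- c(1L, ceiling(c(0.25, 0.5, 0.75) * n), n)
        dist[(cl - 1) * 5 + 1:5] <- pos[idx] / L * 100
      }
    }
    c(comp, tran, dist)
  })

  c(aac, unlist(per_prop))
}

#' Amphiphilic pseudo amino acid composition
#'
#' A `20 + 2*lambda` vector: the 20 normalized residue frequencies followed
#' by `2*lambda` weighted sequence-order correlation factors, alternating
#' hydrophobicity and hydrophilicity. The factor of rank j for scale H is
#' `tau = (1/(L-j)) * sum_i H(R_i) * H(R_(i+j))`, with both scales
#' standardized over the 20 residues. All components share the denominator
#' `1 + w * sum(tau)`, so the vector sums to 1.
#'
#' @param residues Sanitized residue string of length greater than `lambda`.
#' @param lambda Sequence-order depth (>= 1).
#' @param w Weight of the correlation factors.
#' @inheritParams encode_188d
#' @return Named numeric vector of length `20 + 2*lambda`.
#' @export
encode_apaac <- function(residues, lambda = 30, w = 0.05,
                         tables = aa_property_tables()) {
  codes <- check_codes(residues)
  L <- length(codes)
  if (L <= lambda) {
    abort(sprintf("sequence length %d too short for APAAC lambda = %d (need >= %d)",
                  L, lambda, lambda + 1))
  }
  h1 <- unname(tables$scales$h1)[codes]
  h2 <- unname(tables$scales$h2)[codes]

  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    i <- seq_len(L - j)
    tau[2 * j - 1] <- sum(h1[i] * h1[i + j]) / (L - j)
    tau[2 * j]     <- sum(h2[i] * h2[i + j]) / (L - j)
  }

  f <- tabulate(codes, 20) / L
  denom <- sum(f) + w * sum(tau)
  if (abs(denom) < 1e-12) {
    abort("degenerate APAAC normalization (denominator ~ 0)")
  }
  out <- c(f, w * tau) / denom
  names(out) <- c(paste0("apaac.f.", AA20),
                  paste0("apaac.tau.", seq_len(2 * lambda)))
  out
}

#' Type-1 pseudo amino acid composition
#'
#' A `20 + lambda` vector: normalized residue frequencies followed by
#' `lambda` weighted sequence-order correlation factors
#' `theta_j = (1/(L-j)) * sum_i Theta(R_i, R_(i+j))`, where
#' `Theta(a, b)` averages the squared differences of standardized
#' hydrophobicity, hydrophilicity and side-chain mass between the two
#' residues. Shares the APAAC normalization, so the vector sums to 1.
#'
#' @inheritParams encode_apaac
#' @return Named numeric vector of length `20 + lambda`.
#' @export
encode_paac <- function(residues, lambda = 30, w = 0.05,
                        tables = aa_property_tables()) {
  codes <- check_codes(residues)
  L <- length(codes)
  if (L <= lambda) {
    abort(sprintf("sequence length %d too short for PAAC lambda = %d (need >= %d)",
                  L, lambda, lambda + 1))
  }
  h1 <- unname(tables$scales$h1)[codes]
  h2 <- unname(tables$scales$h2)[codes]
  m  <- unname(tables$scales$m)[codes]

  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    i <- seq_len(L - j)
    theta[j] <- sum((h1[i + j] - h1[i])^2 +
                    (h2[i + j] - h2[i])^2 +
                    (m[i + j] - m[i])^2) / (3 * (L - j))
  }

  f <- tabulate(codes, 20) / L
  denom <- sum(f) + w * sum(theta)
  out <- c(f, w * theta) / denom
  names(out) <- c(paste0("paac.f.", AA20),
                  paste0("paac.theta.", seq_len(lambda)))
  out
}

#' k-spaced conjoint triad descriptor
#'
#' Residues are mapped to the 7 conjoint-triad classes; for each spacing k
#' in `0..kmax` the encoder counts class triples `(s_i, s_(i+k+1),
#' s_(i+2(k+1)))` over all valid windows, giving a 343-cell block per k.
#' Each block is normalized per the conjoint-triad convention,
#' `(c - min) / max` over the block (`norm = "minmax"`); an all-zero block
#' stays zero. `norm = "window"` divides counts by the window count
#' instead.
#'
#' @param residues Sanitized residue string with `L >= 2*kmax + 3`.
#' @param kmax Largest spacing (>= 0).
#' @param norm Block normalization, `"minmax"` or `"window"`.
#' @inheritParams encode_188d
#' @return Named numeric vector of length `343 * (kmax + 1)`.
#' @export
encode_ksctriad <- function(residues, kmax = 0,
                            norm = c("minmax", "window"),
                            tables = aa_property_tables()) {
  norm <- match.arg(norm)
  codes <- check_codes(residues)
  L <- length(codes)
  if (L < 2 * kmax + 3) {
    abort(sprintf("sequence length %d too short for KSCTriad kmax = %d (need >= %d)",
                  L, kmax, 2 * kmax + 3))
  }
  tri <- unname(tables$triad)[codes]
  cell_names <- paste0(rep(1:7, each = 49),
                       rep(rep(1:7, each = 7), 7),
                       rep(1:7, 49))
  out <- lapply(0:kmax, function(k) {
    g <- k + 1L
    i <- seq_len(L - 2L * g)
    idx <- (tri[i] - 1L) * 49L + (tri[i + g] - 1L) * 7L + tri[i + 2L * g]
    counts <- tabulate(idx, 343)
    v <- if (norm == "minmax") {
      if (max(counts) > 0) (counts - min(counts)) / max(counts) else numeric(343)
    } else {
      counts / (L - 2L * g)
    }
    stats::setNames(v, paste0("ksctriad.k", k, ".", cell_names))
  })
  unlist(out)
}

#' Composition of k-spaced amino acid group pairs
#'
#' Residues are mapped to five side-chain groups (aliphatic, aromatic,
#' positively charged, negatively charged, uncharged); for each spacing k
#' in `0..kmax` the encoder counts ordered group pairs `(g_i, g_(i+k+1))`
#' and divides by the number of windows `L - k - 1`, so each 25-cell
#' k-block sums to 1.
#'
#' @param residues Sanitized residue string with `L >= kmax + 2`.
#' @param kmax Largest spacing (>= 0).
#' @inheritParams encode_188d
#' @return Named numeric vector of length `25 * (kmax + 1)`.
#' @export
encode_cksaagp <- function(residues, kmax = 5,
                           tables = aa_property_tables()) {
  codes <- check_codes(residues)
  L <- length(codes)
  if (L < kmax + 2) {
    abort(sprintf("sequence length %d too short for CKSAAGP kmax = %d (need >= %d)",
                  L, kmax, kmax + 2))
  }
  grp <- unname(tables$group)[codes]
  gn <- tables$group_names
  cell_names <- paste0(rep(gn, each = 5), "|", rep(gn, 5))
  out <- lapply(0:kmax, function(k) {
    i <- seq_len(L - k - 1L)
    idx <- (grp[i] - 1L) * 5L + grp[i + k + 1L]
    v <- tabulate(idx, 25) / (L - k - 1L)
    stats::setNames(v, paste0("cksaagp.k", k, ".", cell_names))
  })
  unlist(out)
}

#' Composition of k-spaced amino acid pairs
#'
#' The ungrouped analogue of [encode_cksaagp()] over the full 20-letter
#' alphabet: one 400-cell block per spacing k, each block the frequency
#' distribution of ordered residue pairs separated by exactly k residues.
#' Provided as the base method behind the group-pair variant; not part of
#' the default mixed feature.
#'
#' @inheritParams encode_cksaagp
#' @return Named numeric vector of length `400 * (kmax + 1)`.
#' @export
encode_cksaap <- function(residues, kmax = 5) {
  codes <- check_codes(residues)
  L <- length(codes)
  if (L < kmax + 2) {
    abort(sprintf("sequence length %d too short for CKSAAP kmax = %d (need >= %d)",
                  L, kmax, kmax + 2))
  }
  cell_names <- paste0(rep(AA20, each = 20), rep(AA20, 20))
  out <- lapply(0:kmax, function(k) {
    i <- seq_len(L - k - 1L)
    idx <- (codes[i] - 1L) * 20L + codes[i + k + 1L]
    v <- tabulate(idx, 400) / (L - k - 1L)
    stats::setNames(v, paste0("cksaap.k", k, ".", cell_names))
  })
  unlist(out)
}

#' Mixed feature vector
#'
#' Concatenates the enabled descriptor blocks in the fixed order `d188`,
#' `apaac`, `ksctriad`, `cksaagp`, `paac`. Errors from an individual
#' encoder are re-raised naming the failing block.
#'
#' @param residues Sanitized residue string meeting every enabled block's
#'   length requirement (see [min_sequence_length()]).
#' @param config An [encoder_config()].
#' @inheritParams encode_188d
#' @return Named numeric vector of length `config_dimension(config)`.
#' @export
encode_mixed <- function(residues, config = encoder_config(),
                         tables = aa_property_tables()) {
  stopifnot(inherits(config, "encoder_config"))
  encoders <- list(
    d188     = function(r) encode_188d(r, tables),
    apaac    = function(r) encode_apaac(r, config$lambda_apaac, config$w_apaac, tables),
    ksctriad = function(r) encode_ksctriad(r, config$kmax_ksctriad,
                                           config$ksctriad_norm, tables),
    cksaagp  = function(r) encode_cksaagp(r, config$kmax_cksaagp, tables),
    paac     = function(r) encode_paac(r, config$lambda_paac, config$w_paac, tables)
  )
  parts <- lapply(config$blocks, function(b) {
    tryCatch(encoders[[b]](residues), error = function(e) {
      abort(sprintf("encoder '%s' failed: %s", b, conditionMessage(e)))
    })
  })
  unlist(parts)
}

#' Encode a dataset into a feature table
#'
#' Applies [encode_mixed()] to every sequence of a dataset, producing a
#' wide tibble with one row per sequence: the `id` column, the `label`
#' column if present in the input, then one column per feature in the
#' stable order implied by the configuration. No sequence is silently
#' dropped: any sequence failing a length precondition makes the call
#' error with the offending IDs.
#'
#' @param data A tibble with columns `id`, `residues` and optionally
#'   `label`, e.g. from [read_fasta()] or [load_labeled()].
#' @param config An [encoder_config()].
#' @inheritParams encode_188d
#' @return A tibble of `nrow(data)` rows; use [feature_matrix()] to obtain
#'   the bare numeric matrix.
#' @export
encode_dataset <- function(data, config = encoder_config(),
                           tables = aa_property_tables()) {
  stopifnot(all(c("id", "residues") %in% names(data)))
  if (nrow(data) == 0) {
    abort("cannot encode an empty dataset")
  }
  min_len <- min_sequence_length(config)
  too_short <- data$id[nchar(data$residues) < min_len]
  if (length(too_short) > 0) {
    abort(sprintf(
      "%d sequence(s) shorter than the minimum encodable length %d: %s",
      length(too_short), min_len, paste(head(too_short, 10), collapse = ", ")))
  }
  rows <- lapply(data$residues, encode_mixed, config = config, tables = tables)
  mat <- do.call(rbind, rows)
  out <- tibble(id = data$id)
  if ("label" %in% names(data)) {
    out$label <- data$label
  }
  dplyr::bind_cols(out, as_tibble(as.data.frame(mat, check.names = FALSE)))
}

#' Extract the numeric feature matrix from an encoded dataset
#'
#' @param encoded A tibble from [encode_dataset()].
#' @return A numeric matrix with sequence IDs as row names; the `id` and
#'   `label` columns are dropped.
#' @export
feature_matrix <- function(encoded) {
  meta <- intersect(c("id", "label"), names(encoded))
  mat <- as.matrix(encoded[setdiff(names(encoded), meta)])
  rownames(mat) <- encoded$id
  mat
}
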