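#' Amino-acid property tables used by the descriptor encoders
#'
#' Loads (and caches) the fixed lookup tables behind the five descriptor
#' families: the eight three-class physicochemical partitions of the
#' composition/transition/distribution (CTD) block (hydrophobicity,
#' normalized Van der Waals volume, polarity, polarizability, charge,
#' surface tension, secondary structure, solvent accessibility), the five
#' side-chain groups used by the k-spaced group-pair encoder, the seven
#' conjoint-triad classes, and Chou's per-residue hydrophobicity,
#' hydrophilicity and side-chain-mass scales. The three scales are
#' standardized to mean 0 and unit (population) variance over the 20
#' residues, as the pseudo amino acid composition formulation requires.
#'
#' The tables are shipped as a documented plain-text file
#' (`system.file("extdata", "aa_properties.txt", package = "mhcvote")`) and
#' validated on load: every partition must cover the 20 standard residues
#' exactly once.
#'
#' @return A list with elements:
#' \describe{
#'   \item{ctd}{named list of 8 integer vectors (named by residue, values
#'     in 1..3), in the fixed property order used by [encode_188d()].}
#'   \item{group}{integer vector (named by residue, values 1..5) and
#'     `group_names` giving the five side-chain group labels.}
#'   \item{triad}{integer vector (named by residue, values 1..7).}
#'   \item{scales}{list of standardized numeric vectors `h1`, `h2`, `m`
#'     (named by residue).}
#' }
#' @export
#' @examples
#' tbl <- aa_property_tables()
#' names(tbl$ctd)
#' round(mean(tbl$scales$h1), 12)
aa_property_tables <- function() {
  if (!is.null(.mhcvote$tables)) {
    return(.mhcvote$tables)
  }
  path <- system.file("extdata", "aa_properties.txt", package = "mhcvote")
  if (identical(path, "")) {
    abort("property table file not found in installed package")
  }
  .mhcvote$tables <- parse_property_tables(path)
  .mhcvote$tables
}

ctd_property_order <- c(
  "hydrophobicity", "normwaalsvolume", "polarity", "polarizability",
  "charge", "surfacetension", "secondarystruct", "solventaccess"
)

group_order <- c("aliphatic", "aromatic", "positive", "negative", "uncharged")

parse_property_tables <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  assign_classes <- function(rows, what) {
    cls <- integer(20)
    names(cls) <- AA20
    for (r in rows) {
      members <- strsplit(r$residues, "", fixed = TRUE)[[1]]
      bad <- setdiff(members, AA20)
      if (length(bad) > 0) {
        abort(sprintf("unknown residue '%s' in %s table", bad[1], what))
      }
      cls[members] <- r$class
    }
    if (any(cls == 0L)) {
      abort(sprintf("%s partition does not cover all 20 residues", what))
    }
    cls
  }

  ctd_rows <- fields[vapply(fields, function(f) f[1] == "ctd", logical(1))]
  ctd <- lapply(ctd_property_order, function(prop) {
    rows <- Filter(function(f) f[2] == prop, ctd_rows)
    if (length(rows) != 3) {
      abort(sprintf("CTD property '%s' must have exactly 3 classes", prop))
    }
    covered <- sum(nchar(vapply(rows, `[`, character(1), 4)))
    if (covered != 20) {
      abort(sprintf("CTD property '%s' assigns %d residues, expected 20", prop, covered))
    }
    assign_classes(
      lapply(rows, function(f) list(class = as.integer(f[3]), residues = f[4])),
      prop
    )
  })
  names(ctd) <- ctd_property_order

  grp_rows <- fields[vapply(fields, function(f) f[1] == "group", logical(1))]
  grp_map <- stats::setNames(
    vapply(grp_rows, `[`, character(1), 3),
    vapply(grp_rows, `[`, character(1), 2)
  )
  group <- assign_classes(
    lapply(seq_along(group_order), function(i) {
      list(class = i, residues = unname(grp_map[group_order[i]]))
    }),
    "side-chain group"
  )

  triad_rows <- fields[vapply(fields, function(f) f[1] == "triad", logical(1))]
  triad <- assign_classes(
    lapply(triad_rows, function(f) list(class = as.integer(f[2]), residues = f[3])),
    "conjoint triad"
  )

  scale_rows <- fields[vapply(fields, function(f) f[1] == "scale", logical(1))]
  scales <- lapply(c(h1 = "h1", h2 = "h2", m = "m"), function(which) {
    rows <- Filter(function(f) f[2] == which, scale_rows)
    v <- stats::setNames(
      vapply(rows, function(f) as.numeric(f[4]), numeric(1)),
      vapply(rows, `[`, character(1), 3)
    )
    if (!setequal(names(v), AA20) || length(v) != 20) {
      abort(sprintf("scale '%s' must give one value per standard residue", which))
    }
    v <- v[AA20]
    # population standardization over the 20 residues
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  })

  list(
    ctd = ctd,
    group = group,
    group_names = group_order,
    triad = triad,
    scales = scales
  )
}
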