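#' Species genome parameters
#'
#' Bundle of the genome bookkeeping constants needed to forecast how many
#' copies of a species-specific target sequence a given mass of genomic DNA
#' contains: the number of target copies per monoploid genome (`n`), the
#' ploidy (`x`), and the monoploid genome weight (1C, picograms).
#'
#' The expected number of target copies in a reaction holding `DNA` ng of
#' template is
#' \deqn{c_e = DNA \times 1000 \times n \times \frac{x}{2 \times 1C}}
#'
#' The shipped saffron default (`n = 2/3`, `x = 3`, `1C = 7.87` pg) encodes a
#' target carried on two of the three genome copies of the triploid
#' \emph{Crocus sativus}, giving approximately 127 target copies per ng of
#' template DNA. Note the factor `x/2` together with a per-monoploid `n`:
#' under this convention `n * x` is the number of target copies per nucleus
#' and the division by 2 accounts for 1C being the mass of a single
#' (unreplicated) chromosome set while genomic DNA from somatic tissue is
#' counted per 2C equivalent.
#'
#' @param species_name Species label, free text.
#' @param n_target_copies Target copies per monoploid genome; non-negative,
#'   may be fractional (e.g. `2/3` for a target on two of three subgenomes).
#' @param ploidy Number of chromosome set copies per nucleus; integer >= 1.
#' @param monoploid_weight_pg Monoploid (1C) genome weight in picograms; > 0.
#' @return An object of class `species_genome_params`.
#' @seealso [expected_copies()], [copies_per_ng()], [saffron_params()]
#' @examples
#' p <- species_genome_params("Crocus sativus", 2 / 3, 3, 7.87)
#' copies_per_ng(p) # ~127
#' @export
species_genome_params <- function(species_name, n_target_copies, ploidy,
                                  monoploid_weight_pg) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  n_target_copies <- as.numeric(n_target_copies)
  ploidy <- as.numeric(ploidy)
  monoploid_weight_pg <- as.numeric(monoploid_weight_pg)
  if (length(n_target_copies) != 1L || !is.finite(n_target_copies) ||
    n_target_copies < 0) {
    stop("'n_target_copies' must be a single finite number >= 0", call. = FALSE)
  }
  if (length(ploidy) != 1L || !is.finite(ploidy) || ploidy < 1 ||
    ploidy != round(ploidy)) {
    stop("'ploidy' must be a single integer >= 1", call. = FALSE)
  }
  if (length(monoploid_weight_pg) != 1L || !is.finite(monoploid_weight_pg) ||
    monoploid_weight_pg <= 0) {
    stop("'monoploid_weight_pg' must be a single finite number > 0",
      call. = FALSE
    )
  }
  structure(
    list(
      species_name = species_name,
      n_target_copies = n_target_copies,
      ploidy = as.integer(ploidy),
      monoploid_weight_pg = monoploid_weight_pg
    ),
    class = "species_genome_params"
  )
}

#' @export
print.species_genome_params <- function(x, ...) {
  cat(sprintf(
    "<species_genome_params> %s: n = %g, ploidy = %d, 1C = %g pg (%.2f copies/ng)\n",
    x$species_name, x$n_target_copies, x$ploidy, x$monoploid_weight_pg,
    copies_per_ng(x)
  ))
  invisible(x)
}

#' Built-in saffron (Crocus sativus) genome parameters
#'
#' Triploid, monoploid genome weight 7.87 pg, target present on two of the
#' three genome copies (`n = 2/3`), yielding approximately 127 target copies
#' per ng of template DNA.
#'
#' @return A [species_genome_params()] object.
#' @export
saffron_params <- function() {
  species_genome_params("Crocus sativus", 2 / 3, 3L, 7.87)
}

#' Forecast expected target copies from template mass
#'
#' Converts the mass of genomic DNA template in a reaction into the number of
#' target-sequence copies it is expected to contain, given the species'
#' genome parameters:
#' `ce = dna_ng * 1000 * n * x / (2 * 1C)` with 1C in picograms.
#'
#' @param dna_ng Template DNA mass in the reaction, in nanograms (>= 0);
#'   vectorised.
#' @param params A [species_genome_params()] object.
#' @return Expected copies `ce`, same length as `dna_ng`. Linear in `dna_ng`.
#' @examples
#' expected_copies(10, saffron_params()) # ~1271 copies
#' @export
expected_copies <- function(dna_ng, params) {
  stopifnot(inherits(params, "species_genome_params"))
  dna_ng <- as.numeric(dna_ng)
  if (any(!is.finite(dna_ng)) || any(dna_ng < 0)) {
    stop("'dna_ng' must be finite and >= 0", call. = FALSE)
  }
  dna_ng * 1000 * params$n_target_copies * params$ploidy /
    (2 * params$monoploid_weight_pg)
}

#' Expected target copies per nanogram of template
#'
#' The species constant `1000 * n * x / (2 * 1C)`; equals
#' `expected_copies(1, params)`.
#'
#' @inheritParams expected_copies
#' @return Copies per ng (scalar, >= 0).
#' @export
copies_per_ng <- function(params) {
  expected_copies(1, params)
}

#' Parse a rational-number string
#'
#' Accepts plain decimals (`"0.5"`) and fractions (`"2/3"`); fractions are
#' evaluated as numerator/denominator in double precision so that `"2/3"`
#' is bit-identical to the R expression `2/3`.
#'
#' @param x Character vector.
#' @return Numeric vector.
#' @export
parse_rational <- function(x) {
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop(sprintf("cannot parse rational '%s'", s), call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(trimws(parts[1])))
      den <- suppressWarnings(as.numeric(trimws(parts[2])))
      if (is.na(num) || is.na(den) || den == 0) {
        stop(sprintf("cannot parse rational '%s'", s), call. = FALSE)
      }
      num / den
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop(sprintf("cannot parse number '%s'", s), call. = FALSE)
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a species parameter registry
#'
#' The registry is a CSV file with one record per species and columns
#' `species`, `n_target_copies`, `ploidy`, `monoploid_weight_pg`.
#' `n_target_copies` accepts fraction strings such as `"2/3"` (parsed
#' bit-exactly, see [parse_rational()]).
#'
#' @param path Path to the CSV registry.
#' @return Named list of [species_genome_params()] objects, keyed by species.
#' @export
read_species_registry <- function(path) {
  df <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    strip.white = TRUE
  )
  needed <- c("species", "n_target_copies", "ploidy", "monoploid_weight_pg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(
      sprintf(
        "species registry '%s' lacks column(s): %s", path,
        paste(missing, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  if (nrow(df) == 0L) stop("species registry has no records", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    species_genome_params(
      species_name = df$species[i],
      n_target_copies = parse_rational(df$n_target_copies[i]),
      ploidy = as.integer(df$ploidy[i]),
      monoploid_weight_pg = as.numeric(df$monoploid_weight_pg[i])
    )
  })
  names(out) <- df$species
  out
}

#' Look up a species, falling back to the built-in saffron entry
#'
#' @param species Species name.
#' @param registry_path Optional path to a registry CSV; when `NULL` only the
#'   built-in saffron entry is available.
#' @return A [species_genome_params()] object.
#' @export
lookup_species <- function(species, registry_path = NULL) {
  if (!is.null(registry_path)) {
    reg <- read_species_registry(registry_path)
    if (species %in% names(reg)) {
      return(reg[[species]])
    }
  }
  if (identical(species, "Crocus sativus") || identical(species, "saffron")) {
    return(saffron_params())
  }
  stop(sprintf("species '%s' not found in registry", species), call. = FALSE)
}
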