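#' Map pipeline roles to VCF sample names
#'
#' A bulked-segregant run of a dominant-mutant F1 cross involves five
#' sequenced samples: the red (mutant, heterozygous dominant) parent, the
#' green parent, the original cultivar the mutant arose from, and the two
#' phenotype-selected F1 pools. Downstream functions address samples by
#' *role*; this object records which VCF sample column carries each role,
#' which phenotype is dominant, and which parent is the female of the cross
#' (the female parent defines the `M` allele of the SNP index).
#'
#' @param red_parent,green_parent,original,red_pool,green_pool VCF sample
#'   names (single strings) for the five roles.
#' @param dominant_color Label of the dominant phenotype. Default `"red"`.
#' @param female_role,male_role Which parent role is the female/male of the
#'   cross. Must be `"red_parent"` and `"green_parent"` in some order.
#'   Defaults reflect a green (female) x red (male) cross.
#' @return An object of class `bsa_roles`: a named list with elements
#'   `samples` (named character vector role -> sample), `dominant_color`,
#'   `female_role`, `male_role`.
#' @examples
#' sample_roles(
#'   red_parent = "ZaosuRed", green_parent = "KualaPear",
#'   original = "Zaosu", red_pool = "RedPool", green_pool = "GreenPool"
#' )
#' @export
sample_roles <- function(red_parent, green_parent, original,
                         red_pool, green_pool,
                         dominant_color = "red",
                         female_role = "green_parent",
                         male_role = "red_parent") {
  samples <- c(
    red_parent = red_parent, green_parent = green_parent,
    original = original, red_pool = red_pool, green_pool = green_pool
  )
  if (!all(nzchar(samples)) || anyNA(samples)) {
    abort("All five roles must map to non-empty sample names.")
  }
  if (anyDuplicated(samples)) {
    abort("Role sample names must be distinct.")
  }
  parent_roles <- c("red_parent", "green_parent")
  if (!setequal(c(female_role, male_role), parent_roles)) {
    abort("`female_role` and `male_role` must be the two parent roles.")
  }
  structure(
    list(
      samples = samples,
      dominant_color = dominant_color,
      female_role = female_role,
      male_role = male_role
    ),
    class = "bsa_roles"
  )
}

#' @method print bsa_roles
#' @export
print.bsa_roles <- function(x, ...) {
  cat("<bsa_roles>\n")
  for (r in names(x$samples)) {
    tag <- if (r == x$female_role) " (female)"
    else if (r == x$male_role) " (male)" else ""
    cat(sprintf("  %-13s -> %s%s\n", r, x$samples[[r]], tag))
  }
  cat("  dominant color:", x$dominant_color, "\n")
  invisible(x)
}

#' Roles used by the bundled simulator
#'
#' Convenience constructor for the sample names `simulate_pools()` writes.
#' @return A `bsa_roles` object.
#' @export
default_roles <- function() {
  sample_roles(
    red_parent = "red_parent", green_parent = "green_parent",
    original = "original", red_pool = "red_pool", green_pool = "green_pool"
  )
}

#' Read a sample-role configuration file
#'
#' Accepts either a YAML mapping or a two-column TSV (`role<TAB>sample`).
#' Recognised keys are the five role names plus the optional
#' `dominant_color`, `female_role` and `male_role`.
#'
#' @param path Path to the configuration file.
#' @return A `bsa_roles` object.
#' @export
read_sample_roles <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    kv <- yaml::read_yaml(path)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("key", "value"),
                            colClasses = "character")
    kv <- as.list(setNames(df$value, df$key))
  }
  need <- c("red_parent", "green_parent", "original", "red_pool", "green_pool")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    abort(paste0("Role configuration is missing role(s): ",
                 paste(missing, collapse = ", ")))
  }
  do.call(sample_roles, kv[intersect(
    c(need, "dominant_color", "female_role", "male_role"), names(kv)
  )])
}

role_names <- function() {
  c("red_parent", "green_parent", "original", "red_pool", "green_pool")
}

ad_col <- function(role) paste0("ad_", role)
gt_col <- function(role) paste0("gt_", role)
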