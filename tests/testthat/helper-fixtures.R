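# shared fixtures built in code

extdata <- function(name) {
  system.file("extdata", name, package = "bsascan", mustWork = TRUE)
}

table_roles <- function() {
  sample_roles(
    red_parent = "ZaosuRed", green_parent = "KualaPear",
    original = "Zaosu", red_pool = "RedPool", green_pool = "GreenPool"
  )
}

# deterministic ORF of n_codons total codons (incl. final stop), no
# internal stop codon
make_orf <- function(n_codons, seed = 1) {
  withr::with_seed(seed, {
    codons <- apply(
      matrix(sample(c("A", "C", "G", "T"), 3 * (n_codons - 1), replace = TRUE),
             ncol = 3), 1, paste, collapse = ""
    )
    codons[codons %in% c("TAA", "TAG", "TGA")] <- "AAA"
    paste0("ATG", paste(codons[-1], collapse = ""), "TAA")
  })
}

# minimal in-memory variant table; ads: named list role -> c(ref, alt) or NULL
make_variant <- function(chrom = "Chr1", pos = 100L, ref = "A", alt = "T",
                         ads = list()) {
  v <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    alts = list(strsplit(alt, ",", fixed = TRUE)[[1]])
  )
  v$n_alt <- lengths(v$alts)
  v$variant_class <- classify_variant(v$ref, v$alts)
  for (role in c("red_parent", "green_parent", "original",
                 "red_pool", "green_pool")) {
    ad <- ads[[role]]
    v[[paste0("ad_", role)]] <- list(if (is.null(ad)) NULL else as.integer(ad))
  }
  v
}

# fast small simulation shared by pipeline-level tests
small_sim <- function(seed = 1) {
  simulate_pools(cross_config(
    chrom_lengths = c(Chr4 = 8e6), marker_spacing = 2e4,
    causal_pos = 5e6, seed = seed
  ))
}
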