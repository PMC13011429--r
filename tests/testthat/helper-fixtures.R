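# Shared helpers for building small deterministic fixtures in tests.

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

SITE_ANTICODONS_test <- function(site) intronaut:::SITE_ANTICODONS[[site]]

# Small per-phylum profile keeping end-to-end pipeline tests fast.
small_profile <- function() {
  tibble::tibble(
    phylum = c("PhyA", "PhyB"),
    n_genomes = c(8L, 6L),
    rate_groupI = c(0.5, 0.4),
    rate_groupII = c(0, 0.3),
    site_probs = list(
      c("35/36" = 0.7, "33/34" = 0.3),
      c("33/34" = 0.5, "36/37" = 0.5)
    )
  )
}
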