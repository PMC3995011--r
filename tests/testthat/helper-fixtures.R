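# Shared fixtures: the packaged architecture and small constructors used
# across the suite. All randomness in tests is seeded explicitly.

ARCH <- default_architecture()
P1 <- ARCH$loci[[1]]
AB1_X <- ab1_offset(ARCH)

het <- function(kind, x = AB1_X) {
  diploid_genotype(structural_allele("NORMAL"), structural_allele(kind, x))
}

truth_category <- function(allele_class) {
  ifelse(allele_class == "NORMAL", "NORMAL",
         ifelse(allele_class %in% c("DEL_B", "DEL_A"), "DELETION_B",
                "DUPLICATION_B"))
}

# Published per-stratum deletion-carrier counts (a, b, c, d)
swe_table <- function() contingency_2x2(28, 2375, 33, 1236, "sweden")
uk_table <- function() contingency_2x2(9, 1837, 67, 7288, "uk")
us_table <- function() contingency_2x2(11, 1956, 9, 987, "us")

# Offset midway between panel loci i and i+1
between_loci <- function(i, arch = ARCH) {
  (arch$loci[[i]]$offset + arch$loci[[i + 1]]$offset) / 2
}
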