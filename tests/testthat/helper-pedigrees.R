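# Shared fixtures, built in code.

trio_pedigree <- function() {
  pedigree(id = c("dad", "mom", "kid"),
           father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
           sex = c("male", "female", "unknown"),
           affected = c("no", "no", "yes"))
}

sibpair_pedigree <- function() {
  pedigree(id = c("f", "m", "s1", "s2"),
           father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m"),
           sex = c("male", "female", "male", "female"),
           affected = c("no", "no", "yes", "yes"))
}

cousins_pedigree <- function() {
  # two sibs marry in spouses; one child each: the children are first cousins
  pedigree(id = c("gf", "gm", "p1", "p2", "sp1", "sp2", "c1", "c2"),
           father = c(NA, NA, "gf", "gf", NA, NA, "p1", "p2"),
           mother = c(NA, NA, "gm", "gm", NA, NA, "sp1", "sp2"),
           sex = c("male", "female", "male", "male", "female", "female",
                   "unknown", "unknown"),
           affected = c("no", "no", "no", "no", "no", "no", "yes", "yes"))
}

# named dosage vector for one marker over a pedigree
marker_calls <- function(ped, ...) {
  calls <- rep(NA_integer_, nrow(ped))
  names(calls) <- ped$id
  given <- list(...)
  calls[names(given)] <- unlist(given)
  calls
}

# minimal genotype-table data frame builder
make_gtab <- function(ped, dosage_matrix, af = 0.5, cm = NULL,
                      chrom = "1", pos = NULL) {
  M <- nrow(dosage_matrix)
  tab <- data.frame(
    CHROM = chrom,
    POS = if (is.null(pos)) seq_len(M) * 1e6L else pos,
    REF = "A", ALT = "G",
    AF = rep_len(af, M),
    CM = if (is.null(cm)) (seq_len(M) - 1) * 10 else cm,
    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(dosage_matrix)))
    tab[[colnames(dosage_matrix)[j]]] <- dosage_matrix[, j]
  pedscan:::as_genotype_table(tab, colnames(dosage_matrix))
}

# annotated-variant row with sensible pass-everything defaults
annot_variant <- function(chrom = "1", pos = 1000L, ref = "A", alt = "G",
                          gene = "GENE1", category = "missense",
                          kg_eur = NA, gnomad_nfe = 0.01, exac_nfe = NA,
                          cadd = 25, gwava = NA, gerp = NA, spidex = NA,
                          splice_ai = NA, sift = NA, polyphen = NA,
                          mutation_taster = NA, mutation_assessor = NA,
                          fathmm = NA, carriers = "a1,a2") {
  data.frame(CHROM = chrom, POS = pos, REF = ref, ALT = alt, GENE = gene,
             CATEGORY = category, KG_EUR = as.numeric(kg_eur),
             GNOMAD_NFE = as.numeric(gnomad_nfe),
             EXAC_NFE = as.numeric(exac_nfe),
             CADD_PHRED = as.numeric(cadd), GWAVA = as.numeric(gwava),
             GERP = as.numeric(gerp), SPIDEX = as.numeric(spidex),
             SPLICE_AI = as.numeric(splice_ai),
             SIFT = as.character(sift), POLYPHEN = as.character(polyphen),
             MUTATION_TASTER = as.character(mutation_taster),
             MUTATION_ASSESSOR = as.character(mutation_assessor),
             FATHMM = as.character(fathmm),
             CARRIERS = carriers, stringsAsFactors = FALSE)
}
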