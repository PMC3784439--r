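# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data files.

makeCohort <- function(father, mother, child, ...) {
  toMat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)
  TrioCohort(father = toMat(father), mother = toMat(mother),
             child = toMat(child), ...)
}

# TransmissionSummary straight from an X / het-parents pair.
makeSummary <- function(X, het) {
  H <- colSums(het)
  S <- colSums(X)
  new("TransmissionSummary", X = X, hetParents = het,
      H = H, b = (H + S) / 2, c = (H - S) / 2,
      variantIds = paste0("v", seq_len(ncol(X))))
}

# Summary with prescribed per-variant transmitted counts T_j out of H_j,
# realized as H_j single-het families per variant (+1 for transmissions,
# -1 otherwise), padded to a common family count.
makeSummaryFromCounts <- function(T, H) {
  n <- max(H, 1)
  L <- length(H)
  X <- matrix(0, n, L)
  het <- matrix(0, n, L)
  for (j in seq_len(L)) {
    if (H[j] == 0) next
    het[seq_len(H[j]), j] <- 1
    X[seq_len(H[j]), j] <- c(rep(1, T[j]), rep(-1, H[j] - T[j]))
  }
  makeSummary(X, het)
}

# Minimal VCF writer for reader tests: `geno` is a variants x samples matrix
# of GT strings.
writeTinyVcf <- function(path, samples, geno, ref = "A", alt = "T",
                         ids = paste0("v", seq_len(nrow(geno)))) {
  L <- nrow(geno)
  ref <- rep(ref, length.out = L)
  alt <- rep(alt, length.out = L)
  header <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(L), function(i)
    paste(c("1", i, ids[i], ref[i], alt[i], ".", ".", ".", "GT",
            geno[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

writeTinyPed <- function(path, fams) {
  ped <- rbind(
    data.frame(fam = fams, id = paste0(fams, "_f"), fa = "0", mo = "0",
               sex = 1, ph = 1),
    data.frame(fam = fams, id = paste0(fams, "_m"), fa = "0", mo = "0",
               sex = 2, ph = 1),
    data.frame(fam = fams, id = paste0(fams, "_c"),
               fa = paste0(fams, "_f"), mo = paste0(fams, "_m"),
               sex = 0, ph = 2))
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# Complement-swap an entire cohort at the genotype level (children only).
swapCohort <- function(cohort, flips) {
  fa <- fatherGeno(cohort); mo <- motherGeno(cohort); ch <- childGeno(cohort)
  swap <- rep(flips == -1, each = nrow(fa))
  ch2 <- ifelse(swap, fa + mo - ch, ch)
  makeCohort(fa, mo, matrix(ch2, nrow(fa)))
}

# Fixed region model (bypasses drawRegion) for oracle checks.
fixedRegion <- function(mafs, rr, prevalence = 0.01, form = "dominant") {
  reg <- new("RegionModel", mafs = mafs, rr = rr, f0 = NA_real_,
             form = form, functional = rr != 1)
  reg@f0 <- calibrateBaselinePenetrance(reg, prevalence)
  reg
}
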