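## Count ALT alleles in a VCF GT string; NA for any missing allele.
.gtToCount <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  clean <- gsub("\\|", "/", gt)
  known <- clean %in% c("0/0", "0/1", "1/0", "1/1")
  out[clean == "0/0"] <- 0L
  out[clean %in% c("0/1", "1/0")] <- 1L
  out[clean == "1/1"] <- 2L
  bad <- !known & !grepl("\\.", clean)
  if (any(bad))
    stop("unsupported genotype string(s): ",
         paste(unique(clean[bad]), collapse = ", "))
  out
}

#' Read a trio cohort from VCF and PED files
#'
#' Reads biallelic SNVs with \pkg{VariantAnnotation}, pairs samples into
#' father/mother/child trios from a 6-column PED file (family, individual,
#' father, mother, sex, phenotype; children are the rows naming both
#' parents), and counts mutant alleles per genotype.  Under
#' \code{mutantRule = "alt"} the VCF ALT allele is counted; under
#' \code{"minor"} the rarer allele among the parental chromosomes (4n
#' alleles, so ascertained children cannot flip the label), with counts
#' complemented where REF is the minor allele.  Families with a missing
#' genotype at any variant are dropped and the count reported; Mendelian
#' violations are an error naming the family and variant.
#'
#' @param vcfPath path to a VCF of biallelic SNVs.
#' @param pedPath path to a 6-column PED file.
#' @param mutantRule \code{"minor"} or \code{"alt"}.
#' @return A \linkS4class{TrioCohort}; the number of families dropped for
#'   missingness is kept in \code{metadata()$droppedFamilies}.
#' @export
readTrioVcf <- function(vcfPath, pedPath, mutantRule = c("minor", "alt")) {
  mutantRule <- match.arg(mutantRule)
  ped <- utils::read.table(pedPath, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fam", "id", "father", "mother",
                                         "sex", "phenotype"))
  kids <- ped[ped$father != "0" & ped$mother != "0", , drop = FALSE]
  if (nrow(kids) == 0L) stop("PED file defines no father/mother/child trios")
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = "unknown")
  if (nrow(vcf) == 0L) stop("VCF contains no records")
  refA <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altL)
  if (any(nAlt != 1L))
    stop("multiallelic record(s) not supported: ",
         paste(rownames(vcf)[nAlt != 1L], collapse = ", "))
  altA <- as.character(unlist(altL))
  if (any(nchar(refA) != 1L | nchar(altA) != 1L))
    stop("non-SNV record(s) not supported: ",
         paste(rownames(vcf)[nchar(refA) != 1L | nchar(altA) != 1L],
               collapse = ", "))
  gt <- VariantAnnotation::geno(vcf)$GT
  for (col in c("father", "mother", "id")) {
    missing <- setdiff(kids[[col]], colnames(gt))
    if (length(missing) > 0L)
      stop("pedigree references sample(s) absent from the VCF: ",
           paste(missing, collapse = ", "))
  }
  L <- nrow(gt)
  toCounts <- function(samples)
    matrix(.gtToCount(gt[, samples, drop = FALSE]), nrow = L)
  fa <- toCounts(kids$father)
  mo <- toCounts(kids$mother)
  ch <- toCounts(kids$id)
  complete <- colSums(is.na(fa) | is.na(mo) | is.na(ch)) == 0L
  nDropped <- sum(!complete)
  if (nDropped > 0L)
    message(nDropped, " familie(s) dropped for missing genotypes")
  if (!any(complete)) stop("no complete families remain after dropping missingness")
  fa <- fa[, complete, drop = FALSE]
  mo <- mo[, complete, drop = FALSE]
  ch <- ch[, complete, drop = FALSE]
  mutant <- altA
  if (mutantRule == "minor") {
    altFreq <- rowSums(fa + mo) / (4 * ncol(fa))
    flip <- altFreq > 0.5
    if (any(flip)) {
      fa[flip, ] <- 2L - fa[flip, ]
      mo[flip, ] <- 2L - mo[flip, ]
      ch[flip, ] <- 2L - ch[flip, ]
      mutant[flip] <- refA[flip]
    }
  }
  co <- TrioCohort(father = fa, mother = mo, child = ch,
                   variantIds = rownames(vcf),
                   familyIds = kids$fam[complete],
                   positions = BiocGenerics::start(
                     SummarizedExperiment::rowRanges(vcf)),
                   mutantAllele = mutant)
  S4Vectors::metadata(co)$droppedFamilies <- nDropped
  co
}

#' Read a trio cohort from the flat TSV dialect
#'
#' One row per family; columns \code{father_v1..father_vL},
#' \code{mother_v1..}, \code{child_v1..} of mutant-allele counts in
#' \{0, 1, 2\}.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A \linkS4class{TrioCohort}.
#' @export
readTrioTsv <- function(path) {
  if (file.size(path) %in% c(0L, NA_integer_)) stop("empty cohort file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (nrow(tab) == 0L) stop("cohort file has no families: ", path)
  cols <- colnames(tab)
  roles <- sub("_.*$", "", cols)
  if (!setequal(unique(roles), c("father", "mother", "child")))
    stop("columns must be father_*, mother_*, child_*")
  vids <- unique(sub("^[a-z]+_", "", cols))
  for (role in c("father", "mother", "child")) {
    want <- paste0(role, "_", vids)
    if (!all(want %in% cols))
      stop("missing column(s): ", paste(setdiff(want, cols), collapse = ", "))
  }
  getMat <- function(role) {
    m <- t(as.matrix(tab[, paste0(role, "_", vids), drop = FALSE]))
    bad <- which(!(m %in% c(0, 1, 2)) | is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("invalid genotype at row %d, column %s_%s (must be 0, 1 or 2)",
                   bad[1, 2], role, vids[bad[1, 1]]))
    m
  }
  TrioCohort(father = getMat("father"), mother = getMat("mother"),
             child = getMat("child"), variantIds = vids,
             familyIds = if (!is.null(rownames(tab)) &&
                             !identical(rownames(tab),
                                        as.character(seq_len(nrow(tab)))))
               rownames(tab) else NULL)
}

#' Write a trio cohort in the flat TSV dialect
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTrioTsv <- function(cohort, path) {
  stopifnot(is(cohort, "TrioCohort"))
  vids <- rownames(cohort)
  tab <- cbind(t(fatherGeno(cohort)), t(motherGeno(cohort)),
               t(childGeno(cohort)))
  colnames(tab) <- c(paste0("father_", vids), paste0("mother_", vids),
                     paste0("child_", vids))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trio cohort as VCF plus PED
#'
#' Emits a minimal single-chromosome VCF (mutant allele as ALT, genotypes
#' unphased) and the matching 6-column PED, the end-to-end input format of
#' the command-line interface.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param vcfPath,pedPath output paths.
#' @return Invisibly, \code{vcfPath}.
#' @export
writeTrioVcf <- function(cohort, vcfPath, pedPath) {
  stopifnot(is(cohort, "TrioCohort"))
  L <- nVariants(cohort); n <- nFamilies(cohort)
  fams <- colnames(cohort)
  samples <- as.vector(rbind(paste0(fams, "_f"), paste0(fams, "_m"),
                             paste0(fams, "_c")))
  gtOf <- function(m) matrix(c("0/0", "0/1", "1/1")[m + 1L], nrow = L)
  gt <- matrix("", L, 3L * n)
  gt[, seq(1L, 3L * n, by = 3L)] <- gtOf(fatherGeno(cohort))
  gt[, seq(2L, 3L * n, by = 3L)] <- gtOf(motherGeno(cohort))
  gt[, seq(3L, 3L * n, by = 3L)] <- gtOf(childGeno(cohort))
  rd <- SummarizedExperiment::rowData(cohort)
  pos <- if ("position" %in% colnames(rd)) rd$position else seq_len(L)
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(1, pos, rownames(cohort), "A", "T", ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcfPath)
  ped <- rbind(
    data.frame(fam = fams, id = paste0(fams, "_f"), father = "0",
               mother = "0", sex = 1L, phenotype = 1L),
    data.frame(fam = fams, id = paste0(fams, "_m"), father = "0",
               mother = "0", sex = 2L, phenotype = 1L),
    data.frame(fam = fams, id = paste0(fams, "_c"),
               father = paste0(fams, "_f"), mother = paste0(fams, "_m"),
               sex = 0L, phenotype = 2L))
  utils::write.table(ped, pedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(vcfPath)
}

.resultFields <- function(res, name) {
  out <- list(test = name, statistic = res@statistic, p_value = res@pValue,
              n_perm = res@nPerm, seed = res@seed)
  if (is(res, "TrioLrtResult")) {
    out$pi_hat <- res@piHat
    out$gamma <- res@gamma
  }
  out
}

#' Write test results to TSV or JSON
#'
#' One record per test with its name, statistic, permutation p-value,
#' permutation count and seed (plus \code{pi_hat} and \code{gamma} for the
#' likelihood-ratio test).  Numeric values are written with 17 significant
#' digits so output is bit-stable across runs with identical inputs and
#' round-trips through \code{\link{readResults}}.
#'
#' @param results non-empty named list of \linkS4class{TrioTestResult}
#'   objects.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return Invisibly, the path.
#' @export
writeResults <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (length(results) == 0L) stop("results must be non-empty")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be named by test")
  recs <- lapply(names(results), function(nm)
    .resultFields(results[[nm]], nm))
  if (format == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    hasLrt <- any(vapply(recs, function(r) !is.null(r$pi_hat), logical(1)))
    cols <- c("test", "statistic", "p_value", "n_perm", "seed",
              if (hasLrt) c("pi_hat", "gamma"))
    lines <- vapply(recs, function(r) {
      vals <- vapply(cols, function(cn) {
        v <- r[[cn]]
        if (is.null(v)) return("NA")
        if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v)
        else as.character(v)
      }, character(1))
      paste(vals, collapse = "\t")
    }, character(1))
    writeLines(c(paste(cols, collapse = "\t"), lines), path)
  }
  invisible(path)
}

#' Read test results written by \code{\link{writeResults}}
#'
#' @param path input path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return Named list of \linkS4class{TrioTestResult} /
#'   \linkS4class{TrioLrtResult} objects.
#' @export
readResults <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  recs <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, , drop = FALSE]))
  }
  out <- list()
  for (r in recs) {
    if (!is.null(r$pi_hat) && !is.na(r$pi_hat)) {
      out[[r$test]] <- new("TrioLrtResult", method = r$test,
                           statistic = as.numeric(r$statistic),
                           pValue = as.numeric(r$p_value),
                           nPerm = as.integer(r$n_perm),
                           seed = as.integer(r$seed),
                           piHat = as.numeric(r$pi_hat),
                           gamma = as.numeric(r$gamma))
    } else {
      out[[r$test]] <- new("TrioTestResult", method = r$test,
                           statistic = as.numeric(r$statistic),
                           pValue = as.numeric(r$p_value),
                           nPerm = as.integer(r$n_perm),
                           seed = as.integer(r$seed))
    }
  }
  out
}
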