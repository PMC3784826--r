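# PLINK-style PED/MAP text input and output.
#
# Internal conventions:
#   * genotype calls count MINOR alleles (0/1/2, NA = missing), oriented
#     per SNP so that the counted allele has frequency <= 0.5;
#   * phenotype is 0 = unaffected, 1 = affected, NA = missing
#     (PED column 6 uses 1/2/0 or -9);
#   * missing-allele and missing-parent marker is "0".

MISSING_MARKER <- "0"

#' Construct a genotype matrix
#'
#' A `genotype_matrix` is an integer matrix of minor-allele counts with SNPs
#' in rows and subjects in columns, carrying a SNP map (`snp_id`, `chr`, `bp`)
#' as an attribute.  Row order is MAP order, column order is PED order; both
#' are preserved by every operation in the package.
#'
#' @param calls integer matrix, SNPs x subjects, entries in `{0, 1, 2, NA}`.
#' @param map data frame with columns `snp_id`, `chr`, `bp` (one row per SNP).
#' @param subject_ids character vector of subject identifiers.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, map, subject_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(map), ncol(calls) == length(subject_ids))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ", subject_ids[duplicated(subject_ids)][1L])
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp ids in map")
  if (any(calls < 0L, na.rm = TRUE) || any(calls > 2L, na.rm = TRUE))
    stop("genotype calls must be 0, 1, 2 or NA")
  rownames(calls) <- map$snp_id
  colnames(calls) <- subject_ids
  structure(calls,
            map = data.frame(snp_id = as.character(map$snp_id),
                             chr = map$chr, bp = map$bp,
                             stringsAsFactors = FALSE),
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d subjects\n", nrow(x), ncol(x)))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x))))
  invisible(x)
}

#' SNP map of a genotype matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @return Data frame with columns `snp_id`, `chr`, `bp`.
#' @export
snp_map <- function(genotypes) attr(genotypes, "map")

# Subset a genotype_matrix keeping the map attribute in step.
subset_genotypes <- function(genotypes, snps = NULL, subjects = NULL) {
  map <- snp_map(genotypes)
  x <- unclass(genotypes)
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp_id)
    x <- x[snps, , drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  if (!is.null(subjects)) x <- x[, subjects, drop = FALSE]
  genotype_matrix(x, map, colnames(x))
}

#' Construct a pedigree table
#'
#' Per-subject family structure, sex, stratum label and binary phenotype.
#' `father_id`/`mother_id` equal to `"0"` mean "no parent recorded";
#' non-missing parent references must resolve within the table.
#'
#' @param family_id,individual_id,father_id,mother_id character vectors.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param phenotype 0 (unaffected), 1 (affected) or NA.
#' @param stratum text label, e.g. a recruitment centre; crossed with sex
#'   when tests are stratified.
#' @return Data frame of class `pedigree_table`.
#' @export
pedigree_table <- function(family_id, individual_id, father_id, mother_id,
                           sex = "unknown", phenotype = NA_integer_,
                           stratum = "all") {
  ped <- data.frame(family_id = as.character(family_id),
                    individual_id = as.character(individual_id),
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    sex = as.character(sex),
                    stratum = as.character(stratum),
                    phenotype = as.integer(phenotype),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped[c("family_id", "individual_id")]))
    stop("duplicate (family_id, individual_id) pairs in pedigree")
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual ids in pedigree")
  if (!all(ped$sex %in% c("male", "female", "unknown")))
    stop("sex must be male, female or unknown")
  ok <- is.na(ped$phenotype) | ped$phenotype %in% c(0L, 1L)
  if (!all(ok)) stop("phenotype must be 0, 1 or NA")
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    unresolved <- ref != MISSING_MARKER & !(ref %in% ped$individual_id)
    if (any(unresolved))
      warning(sum(unresolved), " ", col,
              " reference(s) do not resolve within the pedigree")
  }
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

ped_sex_code <- c(male = 1L, female = 2L, unknown = 0L)

#' Read PED/MAP files
#'
#' Parses whitespace-delimited PLINK-style text pedigree (PED) and marker map
#' (MAP) files.  Genotypes are oriented to the minor allele: per SNP the
#' counted allele is the rarer one (frequency tie at 0.5 broken towards the
#' lexicographically larger allele; monomorphic SNPs count the absent allele,
#' i.e. all calls 0).  Any allele pair containing the missing code `"0"`
#' becomes a missing call.  PED phenotype 1/2 maps to 0/1; 0 and -9 to NA.
#'
#' @param ped_path path to the PED file (6 leading columns, then two allele
#'   columns per SNP).
#' @param map_path path to the MAP file (chr, snp_id, optional genetic
#'   distance, bp).
#' @param phenotype_path optional TSV with header columns `subject_id`,
#'   `phenotype`, `stratum`; overrides PED column 6 and assigns strata.
#' @return List with components `pedigree` ([pedigree_table()]) and
#'   `genotypes` ([genotype_matrix()]).
#' @export
read_ped <- function(ped_path, map_path, phenotype_path = NULL) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) == 3L) {
    map <- data.frame(chr = map_raw[[1L]], snp_id = map_raw[[2L]],
                      bp = as.numeric(map_raw[[3L]]))
  } else if (ncol(map_raw) >= 4L) {
    map <- data.frame(chr = map_raw[[1L]], snp_id = map_raw[[2L]],
                      bp = as.numeric(map_raw[[4L]]))
  } else stop("MAP file must have 3 or 4 columns")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  nf <- lengths(fields)
  if (any(nf != expected))
    stop(sprintf("PED line %d has %d fields, expected %d (6 + 2 x %d SNPs)",
                 which(nf != expected)[1L], nf[nf != expected][1L],
                 expected, m))
  ped_mat <- do.call(rbind, fields)
  n <- nrow(ped_mat)

  pheno_raw <- ped_mat[, 6L]
  phenotype <- ifelse(pheno_raw == "2", 1L,
                      ifelse(pheno_raw == "1", 0L, NA_integer_))
  sex <- c("male", "female", "unknown")[
    match(ped_mat[, 5L], c("1", "2"), nomatch = 3L)]
  pedigree <- pedigree_table(family_id = ped_mat[, 1L],
                             individual_id = ped_mat[, 2L],
                             father_id = ped_mat[, 3L],
                             mother_id = ped_mat[, 4L],
                             sex = sex, phenotype = phenotype)

  allele1 <- ped_mat[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  allele2 <- ped_mat[, 6L + 2L * seq_len(m), drop = FALSE]
  calls <- matrix(NA_integer_, nrow = m, ncol = n)
  for (j in seq_len(m)) {
    a1 <- allele1[, j]; a2 <- allele2[, j]
    miss <- a1 == MISSING_MARKER | a2 == MISSING_MARKER
    obs <- c(a1[!miss], a2[!miss])
    if (!length(obs)) next                 # all missing: calls stay NA
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("SNP ", map$snp_id[j], " has more than two alleles")
    counted <- orient_counted_allele(obs, alleles)
    if (is.na(counted)) {               # monomorphic: counted allele absent
      calls[j, ] <- 0L
    } else {
      calls[j, ] <- (a1 == counted) + (a2 == counted)
    }
    calls[j, miss] <- NA_integer_
  }
  genotypes <- genotype_matrix(calls, map, pedigree$individual_id)

  if (!is.null(phenotype_path)) {
    ph <- utils::read.table(phenotype_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    idx <- match(pedigree$individual_id, ph$subject_id)
    hit <- !is.na(idx)
    if ("phenotype" %in% names(ph))
      pedigree$phenotype[hit] <- as.integer(ph$phenotype[idx[hit]])
    if ("stratum" %in% names(ph))
      pedigree$stratum[hit] <- ph$stratum[idx[hit]]
  }
  list(pedigree = pedigree, genotypes = genotypes)
}

# Counted (minor) allele for one SNP given the observed allele vector.
# Monomorphic SNPs count the absent allele so every call is 0; frequency
# ties are broken towards the lexicographically larger allele, which keeps
# write_ped()/read_ped() round trips stable.
orient_counted_allele <- function(obs, alleles) {
  if (length(alleles) == 1L) return(NA_character_)  # handled by caller: all 0
  f1 <- mean(obs == alleles[1L])
  if (f1 < 0.5) alleles[1L] else alleles[2L]
}

#' Write PED/MAP files
#'
#' Inverse of [read_ped()]: the major allele is written as `"A"`, the counted
#' minor allele as `"B"`, missing calls as `"0 0"`.  Phenotype 0/1/NA maps to
#' PED codes 1/2/0.
#'
#' @param pedigree a [pedigree_table()].
#' @param genotypes the matching [genotype_matrix()].
#' @param out_prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped <- function(pedigree, genotypes, out_prefix) {
  stopifnot(identical(pedigree$individual_id, colnames(genotypes)))
  map <- snp_map(genotypes)
  map_lines <- sprintf("%s\t%s\t0\t%s", map$chr, map$snp_id,
                       format(map$bp, scientific = FALSE, trim = TRUE))
  writeLines(map_lines, paste0(out_prefix, ".map"))

  pairs <- c("A A", "A B", "B B")
  geno_txt <- matrix("0 0", nrow = nrow(genotypes), ncol = ncol(genotypes))
  ok <- !is.na(genotypes)
  geno_txt[ok] <- pairs[unclass(genotypes)[ok] + 1L]
  pheno_code <- ifelse(is.na(pedigree$phenotype), "0",
                       as.character(pedigree$phenotype + 1L))
  lead <- paste(pedigree$family_id, pedigree$individual_id,
                pedigree$father_id, pedigree$mother_id,
                ped_sex_code[pedigree$sex], pheno_code)
  body <- apply(geno_txt, 2L, paste, collapse = " ")
  writeLines(paste(lead, body), paste0(out_prefix, ".ped"))
  invisible(c(ped = paste0(out_prefix, ".ped"),
              map = paste0(out_prefix, ".map")))
}
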