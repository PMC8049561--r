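#' Genotype matrix container
#'
#' The central data structure of the package: a sites-by-individuals matrix of
#' diploid genotypes together with SNP and sample metadata. Genotypes are
#' stored internally as the count of the alternative (derived) allele, 0, 1 or
#' 2, with `NA` for missing data. Pseudohaploid data contain only 0, 2 and
#' `NA`.
#'
#' @param geno Integer matrix, one row per SNP and one column per individual,
#'   values in `c(0, 1, 2, NA)`.
#' @param snp Data frame of SNP metadata with columns `snp_id`, `chromosome`
#'   (1-22), `genetic_pos` (Morgans, non-decreasing within chromosome),
#'   `physical_pos` (base pairs, strictly increasing within chromosome),
#'   `ref_allele`, `alt_allele`, and optionally `is_transition`.
#' @param ind Data frame of sample metadata with columns `sample_id` (unique),
#'   `population`, and optionally `sex` (`"M"`, `"F"` or `"U"`).
#'
#' @return An object of class `genotype_matrix`: a list with elements `geno`,
#'   `snp` (tibble) and `ind` (tibble).
#' @export
genotype_matrix <- function(geno, snp, ind) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snp <- tibble::as_tibble(snp)
  ind <- tibble::as_tibble(ind)
  if (!"is_transition" %in% names(snp)) snp$is_transition <- NA
  if (!"sex" %in% names(ind)) ind$sex <- "U"
  obj <- structure(list(geno = geno, snp = snp, ind = ind),
                   class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

validate_genotype_matrix <- function(g, check_values = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$geno) != nrow(g$snp)) {
    stop("genotype matrix has ", nrow(g$geno), " rows but snp table has ",
         nrow(g$snp), " entries", call. = FALSE)
  }
  if (ncol(g$geno) != nrow(g$ind)) {
    stop("genotype matrix has ", ncol(g$geno), " columns but ind table has ",
         nrow(g$ind), " entries", call. = FALSE)
  }
  if (check_values) {
    v <- g$geno[!is.na(g$geno)]
    if (length(v) && (min(v) < 0L || max(v) > 2L)) {
      stop("genotype values must be 0, 1, 2 or NA", call. = FALSE)
    }
  }
  if (anyDuplicated(g$ind$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  if (any(!nzchar(g$ind$population))) {
    stop("population labels must be non-empty", call. = FALSE)
  }
  if (nrow(g$snp) > 0) {
    if (any(g$snp$ref_allele == g$snp$alt_allele)) {
      stop("ref and alt alleles must differ", call. = FALSE)
    }
    by_chr <- split(seq_len(nrow(g$snp)), g$snp$chromosome)
    for (idx in by_chr) {
      if (is.unsorted(g$snp$genetic_pos[idx])) {
        stop("genetic positions must be non-decreasing within a chromosome",
             call. = FALSE)
      }
      if (is.unsorted(g$snp$physical_pos[idx], strictly = TRUE)) {
        stop("physical positions must be strictly increasing within a chromosome",
             call. = FALSE)
      }
    }
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  pops <- table(x$ind$population)
  cat("<genotype_matrix> ", nrow(x$snp), " SNPs x ", nrow(x$ind),
      " individuals (", length(pops), " populations)\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat("  chromosomes: ", length(unique(x$snp$chromosome)),
      "; missingness: ", sprintf("%.1f%%", 100 * miss),
      if (is_pseudohaploid(x)) "; pseudohaploid" else "", "\n", sep = "")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
n_snps <- function(g) nrow(g$snp)

#' @rdname genotype_matrix
#' @export
n_individuals <- function(g) nrow(g$ind)

#' @rdname genotype_matrix
#' @export
populations <- function(g) unique(g$ind$population)

#' @rdname genotype_matrix
#' @export
is_pseudohaploid <- function(g) !any(g$geno == 1L, na.rm = TRUE)

#' Subset a genotype matrix by sites and/or individuals
#'
#' @param g A `genotype_matrix`.
#' @param sites Integer or logical index of SNP rows to keep (order preserved).
#' @param individuals Integer or logical index of individuals to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, sites = NULL, individuals = NULL) {
  if (!is.null(sites)) {
    g$geno <- g$geno[sites, , drop = FALSE]
    g$snp <- g$snp[sites, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    g$geno <- g$geno[, individuals, drop = FALSE]
    g$ind <- g$ind[individuals, , drop = FALSE]
  }
  validate_genotype_matrix(g)
}

#' Read a genotype dataset in EIGENSTRAT format
#'
#' Reads the `.geno`/`.snp`/`.ind` triplet written by `write_eigenstrat()` or
#' by other EIGENSTRAT-producing tools. The `.geno` file holds one row per
#' SNP with one character per individual in `{0, 1, 2, 9}`; `9` denotes
#' missing data. On disk the character is, per EIGENSTRAT convention, the
#' count of the *reference* allele; internally genotypes are stored as counts
#' of the *alternative* allele, so values are flipped at this boundary unless
#' `coding = "alt"`.
#'
#' @param prefix Path prefix; `<prefix>.geno`, `<prefix>.snp` and
#'   `<prefix>.ind` must exist.
#' @param coding `"ref"` (EIGENSTRAT convention, default) or `"alt"` if the
#'   `.geno` characters already count alternative alleles.
#' @return A [genotype_matrix()].
#' @export
read_eigenstrat <- function(prefix, coding = c("ref", "alt")) {
  coding <- match.arg(coding)
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (f in files) if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)

  ind <- utils::read.table(files[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample_id", "sex", "population"),
                           colClasses = "character")
  ind <- tibble::as_tibble(ind)[, c("sample_id", "population", "sex")]

  snp_raw <- scan(files[2], quiet = TRUE,
                  what = list(snp_id = character(), chromosome = integer(),
                              genetic_pos = double(), physical_pos = integer(),
                              ref_allele = character(), alt_allele = character()))
  snp <- tibble::as_tibble(snp_raw)

  geno <- read_geno_file(files[1], n_ind = nrow(ind), n_snp = nrow(snp))
  if (coding == "ref") geno <- 2L - geno
  snp$is_transition <- NA
  if (!"sex" %in% names(ind)) ind$sex <- "U"
  obj <- structure(list(geno = geno, snp = snp, ind = ind),
                   class = "genotype_matrix")
  # genotype characters were validated byte-wise during parsing
  validate_genotype_matrix(obj, check_values = FALSE)
}

# Parse a .geno file as raw bytes: rows are fixed-width digit strings.
read_geno_file <- function(path, n_ind, n_snp) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- raw == as.raw(10L)
  starts <- c(1L, which(nl) + 1L)
  ends <- c(which(nl) - 1L, length(raw))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  widths <- ends - starts + 1L
  if (length(starts) != n_snp) {
    stop(path, ": expected ", n_snp, " genotype rows, found ", length(starts),
         call. = FALSE)
  }
  bad <- which(widths != n_ind)
  if (length(bad)) {
    stop(path, ": line ", bad[1], " has ", widths[bad[1]],
         " genotype characters, expected ", n_ind, call. = FALSE)
  }
  body <- raw[!nl]
  vals <- as.integer(body) - 48L
  counts <- tabulate(vals + 1L, nbins = 128)
  bad_bins <- setdiff(which(counts > 0), c(1L, 2L, 3L, 10L))
  if (length(bad_bins) || any(vals < 0L)) {
    first_bad <- which(!(vals %in% c(0L, 1L, 2L, 9L)))[1]
    stop(path, ": invalid genotype character '",
         rawToChar(body[first_bad]), "'", call. = FALSE)
  }
  vals[vals == 9L] <- NA_integer_
  matrix(vals, nrow = n_snp, ncol = n_ind, byrow = TRUE)
}

#' Write a genotype dataset in EIGENSTRAT format
#'
#' Inverse of [read_eigenstrat()]; the round trip is lossless, with missing
#' genotypes written as `9`.
#'
#' @inheritParams read_eigenstrat
#' @param g A [genotype_matrix()].
#' @return Invisibly, `prefix`.
#' @export
write_eigenstrat <- function(g, prefix, coding = c("ref", "alt")) {
  coding <- match.arg(coding)
  validate_genotype_matrix(g)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)

  geno <- g$geno
  if (coding == "ref") geno <- 2L - geno
  geno[is.na(geno)] <- 9L
  bytes <- as.raw(geno + 48L)
  out <- matrix(as.raw(0L), nrow = ncol(g$geno) + 1L, ncol = nrow(g$snp))
  if (nrow(g$snp) > 0) {
    out[seq_len(ncol(g$geno)), ] <- matrix(bytes, nrow = nrow(g$snp),
                                           byrow = FALSE) |> t()
    out[ncol(g$geno) + 1L, ] <- as.raw(10L)
  }
  writeBin(as.vector(out), paste0(prefix, ".geno"))

  snp_lines <- sprintf("%s\t%d\t%.10g\t%d\t%s\t%s",
                       g$snp$snp_id, g$snp$chromosome, g$snp$genetic_pos,
                       g$snp$physical_pos, g$snp$ref_allele, g$snp$alt_allele)
  writeLines(snp_lines, paste0(prefix, ".snp"))

  ind_lines <- sprintf("%s\t%s\t%s", g$ind$sample_id, g$ind$sex, g$ind$population)
  writeLines(ind_lines, paste0(prefix, ".ind"))
  invisible(prefix)
}
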