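#' Read a PED/MAP file pair
#'
#' Parses the PLINK text dialect: the MAP file has four whitespace-separated
#' columns (chromosome, SNP id, genetic position, physical bp position); the
#' PED file has one sample per line with six leading columns
#' (FID IID PAT MAT SEX PHENO) followed by two allele tokens per SNP
#' (A/C/G/T, `0` = missing). Space and tab delimiters are both accepted, and
#' gzip-compressed files are read transparently.
#'
#' Alleles are assigned per SNP as (`allele_a`, `allele_b`) = (major, minor)
#' by observed frequency, ties broken lexicographically (the
#' lexicographically smaller allele becomes `allele_a`), and genotypes are
#' coded as the dosage of `allele_b`. A `0 0` allele pair is a missing call;
#' a half-missing pair such as `A 0` is also treated as missing, with one
#' warning summarising how many such calls were seen. The PED family-ID
#' column is stored as the population label; the MAP genetic-position
#' column is read but ignored (physical positions drive all distances).
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [geno_data] object.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- read_text_lines(map_path)
  if (!length(map_lines)) stop("MAP file is empty: ", map_path, call. = FALSE)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4L)) {
    stop(sprintf("MAP parse error at line %d: expected 4 fields, found %d",
                 which(nf != 4L)[1], nf[nf != 4L][1]), call. = FALSE)
  }
  map_tok <- do.call(rbind, map_tok)
  m <- nrow(map_tok)
  if (anyDuplicated(map_tok[, 2L])) {
    stop("duplicate snp_id in MAP file", call. = FALSE)
  }

  ped_lines <- read_text_lines(ped_path)
  n <- length(ped_lines)
  expected <- 6L + 2L * m

  fam <- character(n); iid <- character(n)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[k]), "[ \t]+")[[1]]
    if (length(tok) != expected) {
      stop(sprintf(
        "PED parse error at line %d: expected %d fields for %d SNPs, found %d",
        k, expected, m, length(tok)), call. = FALSE)
    }
    fam[k] <- tok[1L]; iid[k] <- tok[2L]
    al <- tok[-(1:6)]
    a1[k, ] <- al[c(TRUE, FALSE)]
    a2[k, ] <- al[c(FALSE, TRUE)]
  }
  ok_tok <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% ok_tok) || !all(a2 %in% ok_tok)) {
    bad <- setdiff(unique(c(a1, a2)), ok_tok)
    stop("PED allele tokens outside {A,C,G,T,0}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    warning(sprintf("%d half-missing allele pairs treated as missing",
                    sum(half)), call. = FALSE)
    a1[half] <- "0"; a2[half] <- "0"
  }

  geno <- matrix(NA_integer_, n, m)
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    al <- al[al != "0"]
    tab <- sort(table(al), decreasing = TRUE)
    if (length(tab) > 2L) {
      stop(sprintf("more than 2 alleles at snp_id %s: %s", map_tok[j, 2L],
                   paste(names(tab), collapse = "/")), call. = FALSE)
    }
    if (length(tab) == 0L) next   # all missing: alleles unknown
    nm <- names(tab)
    if (length(tab) == 2L && tab[1L] == tab[2L]) nm <- sort(nm)
    allele_a[j] <- nm[1L]
    if (length(nm) == 2L) allele_b[j] <- nm[2L]
    b <- allele_b[j]
    if (is.na(b)) {
      d <- ifelse(a1[, j] == "0", NA_integer_, 0L)
    } else {
      d <- (a1[, j] == b) + (a2[, j] == b)
      d[a1[, j] == "0"] <- NA_integer_
    }
    geno[, j] <- d
  }

  geno_data(
    geno,
    map = tibble::tibble(
      snp_id = map_tok[, 2L],
      chromosome = map_tok[, 1L],
      position_bp = as.integer(map_tok[, 4L]),
      allele_a = allele_a,
      allele_b = allele_b
    ),
    samples = tibble::tibble(sample_id = iid, population = fam)
  )
}

read_text_lines <- function(path) {
  con <- gzfile(path, "rt")   # reads plain text transparently too
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Write a genotype dataset as a PED/MAP pair
#'
#' Inverse of [read_ped_map()]: reading the written pair back reproduces the
#' genotype codes, sample order, population labels and map exactly. Missing
#' genotypes become `0 0`; at loci whose alleles were never observed the
#' allele token falls back to `A` so the file stays syntactically valid.
#'
#' @param x A [geno_data] object.
#' @param ped_path,map_path Output paths (a `.gz` suffix writes gzip).
#' @return Invisibly, `x`.
#' @export
write_ped_map <- function(x, ped_path, map_path) {
  map_out <- sprintf("%s %s 0 %d", x$map$chromosome, x$map$snp_id,
                     x$map$position_bp)
  write_text_lines(map_out, map_path)

  a <- ifelse(is.na(x$map$allele_a), "A", x$map$allele_a)
  b <- ifelse(is.na(x$map$allele_b), a, x$map$allele_b)
  n <- n_samples(x); m <- n_snps(x)
  lines <- character(n)
  for (k in seq_len(n)) {
    d <- x$genotypes[k, ]
    t1 <- ifelse(is.na(d), "0", ifelse(d == 2L, b, a))
    t2 <- ifelse(is.na(d), "0", ifelse(d >= 1L, b, a))
    lines[k] <- paste(
      x$samples$population[k], x$samples$sample_id[k], "0", "0", "0", "-9",
      if (m) paste(rbind(t1, t2), collapse = " ") else NULL
    )
  }
  write_text_lines(lines, ped_path)
  invisible(x)
}

write_text_lines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Merge genotype datasets on their common SNPs
#'
#' Keeps the intersection of SNP ids present in all inputs (in the first
#' dataset's order) and concatenates samples, preserving population labels.
#' Allele coding is harmonised to the first dataset's (a, b) assignment:
#' where a later dataset coded the same two alleles the other way round its
#' dosages are flipped (`x -> 2 - x`). No strand flipping is attempted —
#' allele sets that are incompatible even after an a/b swap are an error
#' listing the offending SNP ids.
#'
#' @param datasets List of two or more [geno_data] objects with disjoint
#'   sample ids.
#' @return A merged [geno_data].
#' @export
merge_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 2L)
  ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(ids)) {
    stop("sample_ids are not disjoint across datasets", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(datasets, function(d) d$map$snp_id))
  common <- datasets[[1L]]$map$snp_id[datasets[[1L]]$map$snp_id %in% common]
  anchor <- datasets[[1L]][, common]

  pieces <- vector("list", length(datasets))
  pieces[[1L]] <- anchor$genotypes
  for (k in seq_along(datasets)[-1L]) {
    d <- datasets[[k]][, common]
    flip <- harmonise_alleles(anchor$map, d$map)
    g <- d$genotypes
    if (any(flip)) g[, flip] <- 2L - g[, flip]
    pieces[[k]] <- g
  }

  geno_data(
    do.call(rbind, pieces),
    map = anchor$map,
    samples = dplyr::bind_rows(lapply(datasets, function(d) d$samples))
  )
}

# Returns a logical vector: TRUE where the later map's coding must be
# flipped to match the anchor's (a, b) assignment. Monomorphic/unobserved
# loci are matched on their single observed allele.
harmonise_alleles <- function(anchor_map, other_map) {
  m <- nrow(anchor_map)
  flip <- logical(m)
  bad <- character(0)
  for (j in seq_len(m)) {
    aa <- anchor_map$allele_a[j]; ab <- anchor_map$allele_b[j]
    oa <- other_map$allele_a[j];  ob <- other_map$allele_b[j]
    if (is.na(oa)) next                       # nothing observed: codes all NA
    if (!is.na(ob)) {
      if (identical(c(oa, ob), c(aa, ab))) next
      if (identical(c(oa, ob), c(ab, aa))) { flip[j] <- TRUE; next }
      bad <- c(bad, anchor_map$snp_id[j])
    } else {
      # other dataset monomorphic: dosages are all 0 for allele oa
      if (identical(oa, aa) || is.na(aa)) next
      if (identical(oa, ab)) { flip[j] <- TRUE; next }
      bad <- c(bad, anchor_map$snp_id[j])
    }
  }
  if (length(bad)) {
    stop("incompatible alleles (no strand flipping attempted) at: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  flip
}

#' Keep autosomal SNPs only
#'
#' Retains SNPs whose chromosome label is `"1"`..`"29"` (the goat
#' autosomes); everything else (X, Y, MT, unplaced contigs) is dropped.
#'
#' @param x A [geno_data] object.
#' @return A [geno_data] restricted to autosomal SNPs (possibly empty).
#' @export
subset_autosomes <- function(x) {
  x[, x$map$chromosome %in% as.character(1:29)]
}
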