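#' Genotype container
#'
#' A thin container pairing an individuals-by-SNPs dosage matrix (counts of
#' the minor allele, `NA` = missing) with per-SNP metadata.
#'
#' @param dosage numeric/integer matrix with sample ids as rownames and SNP
#'   ids as colnames; entries in `{0, 1, 2, NA}`.
#' @param map data.frame with at least columns `snp`, `chr`, `pos`; optional
#'   `cm`, `morgan`, `contig`, `allele1`, `allele2`.
#' @return object of class `genotypes`.
#' @export
new_genotypes <- function(dosage, map) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  if (nrow(map) != ncol(dosage))
    stop("map rows must match dosage columns")
  if (!all(c("snp", "chr", "pos") %in% names(map)))
    stop("map needs columns snp, chr, pos")
  if (!identical(as.character(map$snp), colnames(dosage)))
    stop("map$snp must equal colnames(dosage)")
  for (col in c("cm", "morgan")) if (is.null(map[[col]])) map[[col]] <- NA_real_
  if (is.null(map$contig)) map$contig <- NA_character_
  if (is.null(map$allele1)) map$allele1 <- "A"
  if (is.null(map$allele2)) map$allele2 <- "B"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in {0, 1, 2, NA}")
  structure(list(dosage = dosage, map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosage)

#' Minor allele frequency per SNP
#'
#' Computed ignoring missing entries; always in \[0, 0.5\].
#' @param genotypes a `genotypes` object (or dosage matrix).
#' @return named numeric vector.
#' @export
maf <- function(genotypes) {
  D <- if (inherits(genotypes, "genotypes")) genotypes$dosage else genotypes
  f <- colMeans(D, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Subset a genotype panel
#'
#' @param genotypes a `genotypes` object.
#' @param snps SNP ids (or column indices) to keep.
#' @param ids sample ids (or row indices) to keep.
#' @return a `genotypes` object.
#' @export
subset_snps <- function(genotypes, snps) {
  j <- if (is.character(snps)) match(snps, genotypes$map$snp) else snps
  if (anyNA(j)) stop("unknown SNP id(s): ",
                     paste(head(snps[is.na(j)], 5), collapse = ", "))
  new_genotypes(genotypes$dosage[, j, drop = FALSE],
                genotypes$map[j, , drop = FALSE])
}

#' @rdname subset_snps
#' @export
subset_samples <- function(genotypes, ids) {
  D <- genotypes$dosage[ids, , drop = FALSE]
  new_genotypes(D, genotypes$map)
}

.split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read PLINK PED/MAP genotypes
#'
#' Parses whitespace-delimited PED/MAP pairs and recodes each SNP to the
#' dosage of its minor allele (the rarer allele in the sample; ties at 0.5
#' count the alphabetically later allele).  `0` alleles mark missing
#' genotypes.
#'
#' @param ped,map paths to the PED and MAP files.
#' @return a `genotypes` object; `map$contig` is `NA` (the MAP format does
#'   not carry contigs).
#' @export
read_plink <- function(ped, map) {
  mp <- read.table(map, header = FALSE,
                   col.names = c("chr", "snp", "cm", "pos"),
                   colClasses = c("character", "character", "numeric",
                                  "numeric"))
  m <- nrow(mp)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  fields <- .split_ws(lines)
  nf <- lengths(fields)
  bad <- which(nf != 6L + 2L * m)
  if (length(bad))
    stop(sprintf(paste0("PED line %d has %d fields; expected %d ",
                        "(6 + 2 x %d MAP SNPs)"),
                 bad[1], nf[bad[1]], 6L + 2L * m, m))
  n <- length(fields)
  tok <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  iid <- tok[, 2]
  if (anyDuplicated(iid)) stop("duplicate individual id in PED: ",
                               iid[duplicated(iid)][1])
  A1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  A2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  D <- matrix(NA_integer_, n, m, dimnames = list(iid, mp$snp))
  a1lab <- a2lab <- character(m)
  for (j in seq_len(m)) {
    a <- c(A1[, j], A2[, j])
    obs <- a[a != "0"]
    al <- sort(unique(obs))
    if (length(al) > 2L)
      stop(sprintf("SNP %s has more than two alleles: %s", mp$snp[j],
                   paste(al, collapse = "/")))
    if (length(al) == 0L) { a1lab[j] <- "0"; a2lab[j] <- "0"; next }
    ok <- A1[, j] != "0" & A2[, j] != "0"
    if (length(al) == 1L) {
      ## monomorphic: the observed allele is the major one, minor unseen
      D[ok, j] <- 0L
      a1lab[j] <- al; a2lab[j] <- "0"
      next
    }
    cnt <- c(sum(obs == al[1]), sum(obs == al[2]))
    ## minor = rarer; tie -> alphabetically later (al is sorted)
    minor <- if (cnt[2] <= cnt[1]) al[2] else al[1]
    major <- setdiff(al, minor)[1]
    D[ok, j] <- (A1[ok, j] == minor) + (A2[ok, j] == minor)
    a1lab[j] <- major; a2lab[j] <- minor
  }
  mp2 <- data.frame(snp = mp$snp, chr = suppressWarnings(as.integer(mp$chr)),
                    pos = mp$pos, cm = mp$cm, morgan = mp$cm / 100,
                    contig = NA_character_, allele1 = a1lab, allele2 = a2lab,
                    stringsAsFactors = FALSE)
  new_genotypes(D, mp2)
}

#' Write PLINK PED/MAP genotypes
#'
#' Writes the counted (minor) allele as `allele2` so that
#' `read_plink(write_plink(x))` reproduces the dosage matrix exactly.
#'
#' @param genotypes a `genotypes` object.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @param pedigree optional pedigree data.frame supplying PAT/MAT/SEX
#'   columns; otherwise written as unknown (0).
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(genotypes, prefix, pedigree = NULL) {
  map <- genotypes$map
  D <- genotypes$dosage
  n <- nrow(D); m <- ncol(D)
  mp <- data.frame(chr = ifelse(is.na(map$chr), 0L, map$chr),
                   snp = map$snp,
                   cm = ifelse(is.na(map$cm), 0, map$cm),
                   pos = map$pos)
  write.table(mp, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(D)
  pat <- mat <- rep("0", n); sex <- rep("0", n)
  if (!is.null(pedigree)) {
    i <- match(ids, pedigree$id)
    pat <- ifelse(is.na(i) | is.na(pedigree$sire[i]), "0", pedigree$sire[i])
    mat <- ifelse(is.na(i) | is.na(pedigree$dam[i]), "0", pedigree$dam[i])
    sex <- ifelse(is.na(i), "0",
                  c(M = "1", F = "2")[as.character(pedigree$sex[i])])
    sex[is.na(sex)] <- "0"
  }
  G <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- D[, j]
    a1 <- map$allele1[j]; a2 <- map$allele2[j]
    G[, 2L * j - 1L] <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
    G[, 2L * j] <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
  }
  lines <- paste(ids, ids, pat, mat, sex, "-9",
                 apply(G, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Topologically sort a pedigree
#'
#' Orders records so that parents precede their offspring (Kahn's
#' algorithm).  Errors on a cycle, listing one offending cycle.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (NA =
#'   unknown) and optionally `sex`.
#' @return the reordered pedigree with attribute `sorted = TRUE`.
#' @export
sort_pedigree <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  par <- cbind(match(pedigree$sire, ids), match(pedigree$dam, ids))
  npar <- rowSums(!is.na(par))
  children <- vector("list", n)
  for (k in 1:2) {
    known <- which(!is.na(par[, k]))
    for (i in known) children[[par[i, k]]] <- c(children[[par[i, k]]], i)
  }
  order_out <- integer(0)
  ready <- which(npar == 0L)
  deg <- npar
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order_out) < n) {
    left <- setdiff(seq_len(n), order_out)
    walk <- left[1]; seen <- walk
    repeat {
      nxt <- par[walk[length(walk)], ]
      nxt <- nxt[!is.na(nxt) & nxt %in% left][1]
      if (is.na(nxt)) break
      if (nxt %in% seen) {
        cyc <- c(seen[which(seen == nxt):length(seen)], nxt)
        stop("pedigree contains a cycle: ",
             paste(ids[cyc], collapse = " -> "))
      }
      walk <- c(walk, nxt); seen <- c(seen, nxt)
    }
    stop("pedigree contains a cycle involving: ",
         paste(ids[left], collapse = ", "))
  }
  out <- pedigree[order_out, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sorted") <- TRUE
  out
}

.is_sorted_pedigree <- function(pedigree) {
  pos <- seq_len(nrow(pedigree))
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  all(is.na(si) | si < pos) && all(is.na(di) | di < pos)
}

#' Read a pedigree table
#'
#' Tab-separated file with header columns `id`, `sire`, `dam` and optionally
#' `sex`; `0`, empty or `NA` mark unknown parents.  The result is
#' topologically sorted (parents first).
#'
#' @param path file path.
#' @return sorted pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$id))
    stop("duplicate individual id in pedigree: ",
         ped$id[duplicated(ped$id)][1])
  for (col in c("sire", "dam"))
    ped[[col]][ped[[col]] %in% c("0", "", "NA")] <- NA_character_
  sort_pedigree(ped)
}

#' Write a pedigree table
#' @param pedigree pedigree data.frame.
#' @param path output path; unknown parents written as `0`.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree
  for (col in c("sire", "dam")) out[[col]][is.na(out[[col]])] <- "0"
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated file with header; must contain an `id` column.  If a
#' pedigree is supplied, ids absent from it are reported in a warning.
#'
#' @param path file path.
#' @param pedigree optional pedigree for the id join check.
#' @return data.frame of phenotypes.
#' @export
read_phenotypes <- function(path, pedigree = NULL) {
  ph <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!"id" %in% names(ph)) stop("phenotype file needs an id column")
  ph$id <- as.character(ph$id)
  if (anyDuplicated(ph$id))
    stop("duplicate individual id in phenotypes: ",
         ph$id[duplicated(ph$id)][1])
  if (!is.null(pedigree)) {
    miss <- setdiff(ph$id, pedigree$id)
    if (length(miss))
      warning("phenotyped id(s) absent from pedigree: ",
              paste(miss, collapse = ", "))
  }
  ph
}

#' Write a phenotype table
#' @param phenotypes data.frame with an `id` column.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
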