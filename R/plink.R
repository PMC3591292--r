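# PLINK 1 binary genotype IO. The .bed payload is SNP-major, 2 bits per
# genotype packed 4 individuals per byte (first individual in the lowest
# bits), preceded by the magic bytes 0x6c 0x1b 0x01. Bit codes, counted as
# dosage of the A1 allele: 00 -> 2, 01 -> missing, 10 -> 1, 11 -> 0.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read PLINK bed/bim/fam files
#'
#' @param prefix path prefix, or explicit `bed`, `bim`, `fam` paths.
#' @param bed,bim,fam optional explicit paths (default `<prefix>.bed` etc).
#' @return a [genotype_matrix()] with dosages counting A1 alleles.
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed")
    bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bimdf <- utils::read.table(bim, stringsAsFactors = FALSE,
                             col.names = c("chr", "id", "cm", "bp", "a1", "a2"))
  famdf <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famdf); m <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic))
    stop("not a SNP-major PLINK bed file (bad magic bytes)")
  bps <- ceiling(n / 4)   # bytes per SNP
  if (length(raw) - 3 != bps * m)
    stop(sprintf("bed payload has %d bytes, expected %d (truncated file or bim/fam mismatch)",
                 length(raw) - 3, bps * m))
  b <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit codes of every byte
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4 * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]  # drop padding rows
  lookup <- c(2, NA, 1, 0)
  X <- matrix(lookup[codes + 1L], n, m)
  genotype_matrix(X, bimdf[, c("chr", "id", "bp", "a1", "a2")],
                  samples = as.character(famdf[[2]]))
}

#' Write PLINK bed/bim/fam files
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return invisibly, the three paths written.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- n_samples(G); m <- n_snps(G)
  v <- G$variants
  utils::write.table(
    data.frame(chr = v$chr, id = v$id, cm = 0, bp = v$bp, a1 = v$a1, a2 = v$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(fid = G$samples, iid = G$samples, pat = 0, mat = 0,
               sex = 0, phe = -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code; pad individuals to a multiple of 4 with code 0
  code_of <- function(x) ifelse(is.na(x), 1L, c(3L, 2L, 0L)[x + 1L])
  codes <- code_of(G$dosages)
  pad <- (4 - n %% 4) %% 4
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, m))
  dim(codes) <- c(4, length(codes) / 4)
  bytes <- as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] +
                  64L * codes[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(.bed_magic, con)
  writeBin(bytes, con)
  close(con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
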