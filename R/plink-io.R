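# PLINK 1.9 binary triple (.bed/.bim/.fam), SNP-major layout. Genotypes are
# packed two bits per sample starting at the low-order bits of each byte:
# 00 = homozygous A1 (dosage 2), 01 = missing, 10 = heterozygous (1),
# 11 = homozygous A2 (0).

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))
.BED_SNP_MAJOR <- as.raw(0x01)

# dosage value for each 2-bit code 0:3
.BED_DECODE <- c(2, NA, 1, 0)

#' Read a PLINK .bed/.bim/.fam genotype panel
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok)) stop("missing PLINK file(s): ", paste(paths[!ok], collapse = ", "))
  bim <- utils::read.table(paths[2], header = FALSE, sep = "\t",
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], .BED_MAGIC)) {
    stop("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != .BED_SNP_MAJOR) stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m) {
    stop(sprintf(".bed size mismatch: expected %d data bytes for %d samples x %d SNPs, found %d",
                 bytes_per_snp * m, n, m, length(body)))
  }
  ints <- as.integer(body)
  # unpack: for byte b, samples get codes (b >> 0) & 3, (b >> 2) & 3, ...
  codes <- matrix(NA_integer_, nrow = 4 * bytes_per_snp, ncol = m)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bytes_per_snp, by = 4), ] <-
      matrix(bitwAnd(bitwShiftR(ints, 2L * k), 3L), nrow = bytes_per_snp)
  }
  dos <- matrix(.BED_DECODE[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n)
  geno_matrix(dos,
              data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                         a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE),
              samples = fam$V2)
}

#' Write a genotype panel as PLINK .bed/.bim/.fam
#'
#' @param G A [geno_matrix()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  n <- n_individuals(G)
  m <- n_snps(G)
  bytes_per_snp <- ceiling(n / 4)
  # dosage -> 2-bit code
  enc <- function(d) {
    code <- integer(length(d))
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code
  }
  out <- raw(3 + bytes_per_snp * m)
  out[1:2] <- .BED_MAGIC
  out[3] <- .BED_SNP_MAJOR
  pad <- 4 * bytes_per_snp - n
  codes <- apply(G$dosages, 2, function(d) c(enc(d), integer(pad)))
  codes <- matrix(codes, nrow = 4, )  # 4 samples per byte, column-wise
  packed <- as.raw(codes[1, ] + bitwShiftL(codes[2, ], 2) +
                   bitwShiftL(codes[3, ], 4) + bitwShiftL(codes[4, ], 6))
  out[-(1:3)] <- packed
  writeBin(out, paste0(prefix, ".bed"))
  bim <- data.frame(G$map$chrom, G$map$id, 0,
                    format(G$map$pos, scientific = FALSE, trim = TRUE),
                    G$map$a1, G$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$samples, G$samples, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
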