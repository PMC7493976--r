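#' Read one ChIP-seq peak dataset
#'
#' Accepts MACS2 narrowPeak (10 columns; the 10th column is the summit offset
#' from the peak start) or BED6 plus an absolute summit column (7 columns).
#' Peaks below the fold-enrichment filter are dropped; if fewer than
#' `min_peaks_per_dataset` survive, the dataset is flagged excluded (the peaks
#' are still returned so the decision is auditable). Coordinates are 0-based
#' half-open throughout; a narrowPeak summit offset of -1 (unknown) falls back
#' to the interval midpoint with a warning.
#'
#' @param path Path to the peak file.
#' @param cfg A [pipeline_config()]; defaults used when `NULL`.
#' @param dataset_id Identifier attached to every peak; defaults to the file
#'   name without extension.
#' @return A tibble with columns `dataset_id, chrom, start, end, summit,
#'   fold_enrichment` and attributes `included` (logical) and `n_raw`.
#' @export
read_peak_dataset <- function(path, cfg = NULL, dataset_id = NULL) {
  cfg <- as_config(cfg)
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  nc <- ncol(raw)
  if (nc == 10L) {
    pk <- tibble::tibble(
      dataset_id = dataset_id,
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]),
      fold_enrichment = as.numeric(raw[[7]]),
      offset = as.integer(raw[[10]])
    )
    unknown <- pk$offset < 0L
    if (any(unknown)) {
      warning(sum(unknown), " peak(s) with summit offset -1 in '", basename(path),
              "'; falling back to the interval midpoint", call. = FALSE)
    }
    pk$summit <- ifelse(unknown,
                        pk$start + (pk$end - pk$start) %/% 2L,
                        pk$start + pk$offset)
    bad <- !unknown & (pk$summit < pk$start | pk$summit >= pk$end)
    if (any(bad)) {
      stop("summit offset outside peak interval at line(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           " of '", path, "'", call. = FALSE)
    }
    pk$offset <- NULL
  } else if (nc == 7L) {
    pk <- tibble::tibble(
      dataset_id = dataset_id,
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]),
      fold_enrichment = as.numeric(raw[[5]]),
      summit = as.integer(raw[[7]])
    )
    bad <- pk$summit < pk$start | pk$summit >= pk$end
    if (any(bad)) {
      stop("summit outside peak interval at line(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           " of '", path, "'", call. = FALSE)
    }
  } else {
    stop("unrecognized peak file format ('", path, "'): expected 10 columns ",
         "(narrowPeak) or 7 (BED6 + summit), got ", nc, call. = FALSE)
  }
  n_raw <- nrow(pk)
  pk <- dplyr::filter(pk, .data$fold_enrichment >= cfg$min_fold_enrichment)
  pk <- dplyr::select(pk, "dataset_id", "chrom", "start", "end", "summit",
                      "fold_enrichment")
  attr(pk, "included") <- nrow(pk) >= cfg$min_peaks_per_dataset
  attr(pk, "n_raw") <- n_raw
  pk
}

#' @rdname read_peak_dataset
#' @param peaks A tibble returned by `read_peak_dataset()`.
#' @export
peak_dataset_included <- function(peaks) {
  isTRUE(attr(peaks, "included"))
}

#' Read and write site sets as BED6
#'
#' Sites are written as BED6 with `name` = site id and `score` = occupancy
#' score (0 when absent); the strand column carries the motif strand when a
#' motif annotation is present. `read_bed()` accepts BED3 or BED6.
#'
#' @param path File path.
#' @return A tibble with columns `chrom, start, end` (+ `name, score, strand`
#'   for BED6).
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  nc <- ncol(raw)
  if (nc < 3L) stop("BED file '", path, "' has fewer than 3 columns",
                    call. = FALSE)
  out <- tibble::tibble(chrom = as.character(raw[[1]]),
                        start = as.integer(raw[[2]]),
                        end = as.integer(raw[[3]]))
  if (nc >= 6L) {
    out$name <- as.character(raw[[4]])
    out$score <- as.numeric(raw[[5]])
    out$strand <- as.character(raw[[6]])
  }
  out
}

#' @rdname read_bed
#' @param sites A site tibble (needs `chrom, start, end`; `site_id`,
#'   `occupancy_score` and `motif_strand` are used when present).
#' @export
write_sites_bed <- function(sites, path) {
  name <- if ("site_id" %in% names(sites)) sites$site_id else
    paste0(sites$chrom, ":", sites$start, "-", sites$end)
  score <- if ("occupancy_score" %in% names(sites)) sites$occupancy_score else
    rep(0L, nrow(sites))
  strand <- if ("motif_strand" %in% names(sites)) {
    ifelse(is.na(sites$motif_strand), ".", sites$motif_strand)
  } else rep(".", nrow(sites))
  df <- data.frame(sites$chrom, sites$start, sites$end, name, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a JASPAR position frequency matrix
#'
#' Accepts the JASPAR text format: an optional `>ID name` header followed by
#' four rows of counts for A, C, G, T, with or without the
#' `A [ 87 167 ... ]` bracket decoration.
#'
#' @param path Path to the PFM file.
#' @return A 4 x width numeric count matrix with rownames `A,C,G,T` and a
#'   `motif_id` attribute.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  motif_id <- NA_character_
  if (length(lines) && startsWith(lines[1], ">")) {
    motif_id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stop("PFM file '", path, "' needs 4 count rows",
                               call. = FALSE)
  parse_row <- function(ln) {
    ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", ln)
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
  }
  rows <- lapply(lines[1:4], parse_row)
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("PFM rows of '", path, "' have unequal widths",
                            call. = FALSE)
  pfm <- do.call(rbind, rows)
  rownames(pfm) <- c("A", "C", "G", "T")
  attr(pfm, "motif_id") <- motif_id
  pfm
}

#' @rdname read_jaspar_pfm
#' @param pfm A 4 x width count matrix.
#' @param motif_id Header identifier.
#' @export
write_jaspar_pfm <- function(pfm, path, motif_id = "MOTIF") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", motif_id), con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(paste0(b, " [ ", paste(format(pfm[b, ], trim = TRUE),
                                      collapse = " "), " ]"), con)
  }
  invisible(path)
}

#' Genome sequence I/O
#'
#' Thin wrappers around Biostrings FASTA handling; the genome is represented
#' as a named [Biostrings::DNAStringSet].
#'
#' @param path FASTA path.
#' @return A `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome
#' @param genome A named `DNAStringSet` (or named character vector).
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a CpG methylation table (Bismark coverage dialect)
#'
#' Columns: chrom, start, end, percent methylated, methylated count,
#' unmethylated count. Positions are interpreted as 0-based (bedGraph-like);
#' `pos` in the returned tibble is the `start` column.
#'
#' @param path File path.
#' @return Tibble with `chrom, pos, meth_level` (percent, 0-100), `coverage`,
#'   `meth_count, unmeth_count`.
#' @export
read_cpg_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) != 6L) {
    stop("CpG table '", path, "' must have 6 columns ",
         "(chrom, start, end, percent, meth, unmeth)", call. = FALSE)
  }
  tibble::tibble(
    chrom = as.character(raw[[1]]),
    pos = as.integer(raw[[2]]),
    meth_level = as.numeric(raw[[4]]),
    meth_count = as.integer(raw[[5]]),
    unmeth_count = as.integer(raw[[6]]),
    coverage = as.integer(raw[[5]]) + as.integer(raw[[6]])
  )
}

#' @rdname read_cpg_table
#' @param cpgs CpG tibble as returned by `read_cpg_table()`.
#' @export
write_cpg_table <- function(cpgs, path) {
  df <- data.frame(cpgs$chrom, cpgs$pos, cpgs$pos + 1L,
                   round(cpgs$meth_level, 6), cpgs$meth_count,
                   cpgs$unmeth_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Signal and expression matrix I/O
#'
#' Matrices are stored as TSV with a `site_id` (or `gene_id`) first column and
#' one column per dataset/sample.
#'
#' @param path File path.
#' @param id_col Name of the identifier column (first column).
#' @return A tibble whose first column is the identifier.
#' @export
read_signal_matrix <- function(path, id_col = "site_id") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  tibble::as_tibble(df)
}

#' @rdname read_signal_matrix
#' @param mat Tibble whose first column is the identifier.
#' @export
write_signal_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Numeric matrix view of an id-keyed signal tibble; rownames = ids.
signal_as_matrix <- function(mat) {
  m <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(mat[[1]])
  m
}

matrix_as_signal <- function(m, id_col = "site_id") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  out
}

#' Mutation table I/O (VCF-like TSV)
#'
#' Columns: chrom, 1-based position, ref, alt, sample id. Positions are
#' converted to 0-based on read and back to 1-based on write.
#'
#' @param path File path.
#' @return Tibble `chrom, pos` (0-based), `ref, alt, sample_id`.
#' @export
read_mutations <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  expected <- c("chrom", "pos", "ref", "alt", "sample")
  if (!all(expected %in% names(raw))) {
    stop("mutation table '", path, "' must have columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    chrom = as.character(raw$chrom),
    pos = as.integer(raw$pos) - 1L,
    ref = as.character(raw$ref),
    alt = as.character(raw$alt),
    sample_id = as.character(raw$sample)
  )
}

#' @rdname read_mutations
#' @param mutations Tibble with 0-based `pos`.
#' @export
write_mutations <- function(mutations, path) {
  df <- data.frame(chrom = mutations$chrom, pos = mutations$pos + 1L,
                   ref = mutations$ref, alt = mutations$alt,
                   sample = mutations$sample_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene model I/O
#'
#' TSV with columns `gene_id, chrom, strand, tss` (0-based TSS coordinate).
#'
#' @param path File path.
#' @return Tibble `gene_id, chrom, strand, tss`.
#' @export
read_gene_models <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tibble::tibble(gene_id = as.character(raw$gene_id),
                 chrom = as.character(raw$chrom),
                 strand = as.character(raw$strand),
                 tss = as.integer(raw$tss))
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sparse contact map I/O
#'
#' Contact maps are stored as sparse bin-pair TSV: `chrom, bin_i, bin_j,
#' count`. On read, entries are folded into the canonical upper triangle
#' (`bin_i <= bin_j`) and duplicates summed.
#'
#' @param path File path.
#' @param bin_size Bin size in bp.
#' @param n_bins Number of bins; inferred from the largest index if `NULL`.
#' @return A `contact_map` object (see [contact_map()]).
#' @export
read_contact_map <- function(path, bin_size = 5000L, n_bins = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  contact_map(chrom = raw$chrom[1],
              entries = tibble::tibble(i = as.integer(raw$bin_i),
                                       j = as.integer(raw$bin_j),
                                       count = as.numeric(raw$count)),
              bin_size = bin_size, n_bins = n_bins)
}

#' @rdname read_contact_map
#' @param map A `contact_map`.
#' @export
write_contact_map <- function(map, path) {
  df <- data.frame(chrom = map$chrom, bin_i = map$entries$i,
                   bin_j = map$entries$j, count = map$entries$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
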