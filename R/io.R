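#' Write vessel centerlines as JSON-lines
#'
#' One vessel per line: subject, eye, image, timepoint, vessel id, label
#' counts and the list of \[x, y\] points. Numbers are serialized at full
#' precision so re-runs are byte-stable.
#'
#' @param segments centerline table ([gen_vasculature()] layout).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centerlines <- function(segments, path) {
  segments <- data.table::as.data.table(segments)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(segments))) {
    rec <- list(subject = segments$subject[i], eye = segments$eye[i],
                image = segments$image[i],
                timepoint = segments$timepoint[i],
                vessel_id = segments$vessel_id[i],
                n_artery_px = segments$n_artery_px[i],
                n_vein_px = segments$n_vein_px[i],
                points = unname(segments$points[[i]]))
    if ("true_type" %in% names(segments)) {
      rec$true_type <- segments$true_type[i]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read vessel centerlines from JSON-lines
#'
#' @param path file written by [write_centerlines()] (or an external
#'   converter emitting the same schema).
#' @return Centerline data.table with a `points` list-column.
#' @export
read_centerlines <- function(path) {
  lines <- readLines(path)
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      stop(sprintf("parse error in %s line %d: %s",
                                   path, i, conditionMessage(e)))
                    })
    need <- c("subject", "eye", "image", "timepoint", "vessel_id",
              "n_artery_px", "n_vein_px", "points")
    miss <- setdiff(need, names(rec))
    if (length(miss) > 0) {
      stop(sprintf("schema mismatch in %s line %d: missing column(s) %s",
                   path, i, paste(miss, collapse = ", ")))
    }
    data.table::data.table(
      subject = rec$subject, eye = rec$eye, image = rec$image,
      timepoint = as.integer(rec$timepoint), vessel_id = rec$vessel_id,
      true_type = if (!is.null(rec$true_type)) rec$true_type
                  else NA_character_,
      n_artery_px = as.integer(rec$n_artery_px),
      n_vein_px = as.integer(rec$n_vein_px),
      points = list(matrix(as.numeric(rec$points), ncol = 2,
                           dimnames = list(NULL, c("x", "y")))))
  })
  data.table::rbindlist(recs)
}

#' Read/write summary statistics and other tabular formats
#'
#' Summary-statistic files use the exact header
#' `CHR SNP BP EA RA FREQ BETA SE P N` (tab-separated; lead-SNP files add
#' `LOCUS_ID`). All positions are 1-based inclusive. Numbers are written
#' at full precision.
#'
#' @param x table to write.
#' @param path file path.
#' @return `path` invisibly (writers); a data.table (readers).
#' @export
write_sumstats <- function(x, path) {
  x <- data.table::as.data.table(x)
  need <- c("CHR", "SNP", "BP", "EA", "RA", "FREQ", "BETA", "SE", "P", "N")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("schema mismatch: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  extra <- intersect("LOCUS_ID", names(x))
  data.table::fwrite(x[, c(need, extra), with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  need <- c("CHR", "SNP", "BP", "EA", "RA", "FREQ", "BETA", "SE", "P", "N")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("schema mismatch in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(x), c(need, "LOCUS_ID", "NEG_LOG10_P"))
  if (length(unknown) > 0) {
    stop(sprintf("schema mismatch in %s: unknown column(s) %s", path,
                 paste(unknown, collapse = ", ")))
  }
  x
}

#' Read and write GMT gene-set files
#'
#' Each line is: set name, description, then tab-separated member genes.
#' Empty sets are preserved.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions.
#' @return Writers return `path` invisibly; [read_gmt()] returns a named
#'   list with a `"descriptions"` attribute.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)]
                 else character(0))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, "", 2)
  sets
}

#' Tabular writers/readers for annotations, expression, MR and catalogue
#'
#' Gene annotations use 1-based inclusive `start`/`end` with explicit
#' `strand`, `tss` and `tes` columns. Expression matrices are written as
#' genes x tissues TSV with a leading `gene` column. MR tables follow the
#' `SNP, CHR, EA, RA, beta_exp, se_exp, p_exp, beta_out, se_out, p_out`
#' layout.
#'
#' @param x object to write.
#' @param path file path.
#' @return `path` invisibly (writers); the parsed object (readers).
#' @export
write_annotation <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  need <- c("gene", "chr", "start", "end", "strand", "tss", "tes")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("schema mismatch in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname write_annotation
#' @export
write_expression <- function(x, path) {
  dt <- data.table::data.table(gene = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(as.matrix(x)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname write_annotation
#' @export
write_mr <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_mr <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  need <- c("SNP", "EA", "RA", "beta_exp", "se_exp", "p_exp", "beta_out",
            "se_out", "p_out")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("schema mismatch in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname write_annotation
#' @export
write_catalogue <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_catalogue <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  if (!all(c("SNP", "TRAIT") %in% names(x))) {
    stop(sprintf("schema mismatch in %s: need SNP and TRAIT columns", path))
  }
  x
}

#' Export genotype dosages as a minimal VCF 4.2 and import dosages back
#'
#' The export writes one sample column per subject with a `DS` (dosage)
#' FORMAT field. The import maps `DS` to dosages directly, or falls back
#' to counting alternate alleles in `GT`; it requires the `vcfR` package.
#'
#' @param dosage subjects x SNPs matrix.
#' @param meta SNP metadata (`snp`, `chr`, `pos`, `ea`, `ra`).
#' @param path file path.
#' @return `path` invisibly (export); a list `dosage`, `meta` (import).
#' @export
write_vcf <- function(dosage, meta, path) {
  meta <- data.table::as.data.table(meta)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"),
             con)
  samples <- rownames(dosage)
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(dosage)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (j in seq_len(ncol(dosage))) {
    writeLines(paste(c(meta$chr[j], meta$pos[j], meta$snp[j], meta$ra[j],
                       meta$ea[j], ".", "PASS", ".", "DS",
                       format(dosage[, j], trim = TRUE)), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dosage <- t(ds)
  colnames(dosage) <- fix$ID
  meta <- data.table::data.table(snp = fix$ID, chr = as.integer(fix$CHROM),
                                 pos = as.integer(fix$POS), ea = fix$ALT,
                                 ra = fix$REF)
  list(dosage = dosage, meta = meta)
}

#' Write GWAS diagnostics as JSON
#'
#' @param diag list from [ldsc_heritability()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(diag, path) {
  out <- list(h2_snp = diag$h2, h2_snp_se = diag$h2_se,
              lambda_gc = diag$lambda_gc, mean_chi2 = diag$mean_chi2,
              intercept = diag$intercept, intercept_se = diag$intercept_se,
              ratio = diag$ratio)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
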