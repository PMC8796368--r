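#' Methylation value matrix
#'
#' Light container for a probes-by-samples methylation matrix. Rows are
#' probes, columns samples; the `scale` attribute records whether values
#' are beta values in (0,1), M values (logit2 of beta), or
#' population-normalized residuals. Missing measurements are `NA`.
#'
#' @param values Numeric matrix with unique rownames (probe ids) and
#'   unique colnames (sample ids).
#' @param scale One of `"beta"`, `"M"`, `"residual"`.
#' @return An object of class `meth_matrix` (a numeric matrix subclass).
#' @export
meth_matrix <- function(values, scale = c("beta", "M", "residual")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop(sprintf("duplicate probe id: '%s'", dup))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop(sprintf("duplicate sample id: '%s'", dup))
  }
  if (scale == "beta") {
    bad <- which(!is.na(values) & (values <= 0 | values >= 1))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(values))
      stop(sprintf("beta values must lie strictly in (0,1); offending probe '%s', sample '%s'",
                   rownames(values)[rc[1]], colnames(values)[rc[2]]))
    }
  }
  structure(values, scale = scale, class = c("meth_matrix", class(values)))
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("Methylation matrix (%s scale): %d probes x %d samples, %.2f%% missing\n",
              attr(x, "scale"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

value_scale <- function(m) attr(m, "scale")

#' Read and write methylation matrices
#'
#' Plain-text matrix exchange: one header row of sample ids, one row per
#' probe with the probe id in the first column. Delimiter is sniffed from
#' the header (tab or comma) unless given. `write_methylation_matrix()`
#' writes at full double precision so that a write/read/write cycle is
#' byte-identical.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma.
#' @param na Missing-value sentinel (default `"NA"`).
#' @param scale Value scale of the stored matrix (default `"beta"`).
#' @return A [meth_matrix()].
#' @export
read_methylation_matrix <- function(path, delim = NULL, na = "NA", scale = "beta") {
  header <- readLines(path, n = 1)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = delim, header = TRUE, na.strings = na,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file must have a probe-id column and at least one sample column")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) & is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d ('%s')",
                   names(vals)[j], bad, vals[[j]][bad]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  meth_matrix(m, scale = scale)
}

#' @rdname read_methylation_matrix
#' @param matrix A [meth_matrix()] to write.
#' @export
write_methylation_matrix <- function(matrix, path, delim = "\t", na = "NA") {
  stopifnot(inherits(matrix, "meth_matrix"))
  txt <- format(unclass(matrix), digits = 17, trim = TRUE, scientific = FALSE)
  txt[is.na(matrix)] <- na
  out <- cbind(probe_id = rownames(matrix), txt)
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Expects a CSV with columns `probe_id`, `chrom` (autosome number 1-22,
#' `chr` prefixes tolerated), `pos` (1-based bp) and `island` (logical or
#' 0/1 CpG-island membership). Probes on non-autosomal chromosomes are
#' dropped with a message, mirroring the usual removal of X/Y probes.
#'
#' @param path CSV file path.
#' @return A tibble with columns `probe_id`, `chrom` (integer), `pos`,
#'   `island`.
#' @export
read_probe_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("probe_id", "chrom", "pos", "island")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df$chrom <- suppressWarnings(as.integer(sub("^chr", "", as.character(df$chrom))))
  keep <- !is.na(df$chrom) & df$chrom >= 1 & df$chrom <= 22
  if (any(!keep)) {
    message(sprintf("dropping %d non-autosomal probe(s) from manifest", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (anyDuplicated(df$probe_id)) {
    stop(sprintf("duplicate probe id in manifest: '%s'",
                 df$probe_id[duplicated(df$probe_id)][1]))
  }
  if (any(df$pos < 1)) stop("manifest positions must be >= 1 (1-based bp)")
  df$island <- as.logical(df$island)
  tibble::as_tibble(df[c("probe_id", "chrom", "pos", "island")])
}

#' Read a sample sheet
#'
#' Expects a CSV with columns `sample_id`, `family_id`, `pair_id`,
#' `zygosity` (MZ/DZ), `sex`, `age` (years), `plate`, `beadchip`.
#'
#' @param path CSV file path.
#' @return A tibble with those columns.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "family_id", "pair_id", "zygosity", "sex", "age",
           "plate", "beadchip")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample id: '%s'", df$sample_id[duplicated(df$sample_id)][1]))
  }
  if (!all(df$zygosity %in% c("MZ", "DZ"))) stop("zygosity must be 'MZ' or 'DZ'")
  tibble::as_tibble(df[req])
}

#' Beta to M value transform (and back)
#'
#' `beta_to_m()` applies the logit2 transform \eqn{\log_2(v/(1-v))} to a
#' beta-scale matrix; `m_to_beta()` inverts it. Missing values pass
#' through.
#'
#' @param matrix A [meth_matrix()] on the appropriate scale.
#' @return A [meth_matrix()] on the other scale.
#' @export
beta_to_m <- function(matrix) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (value_scale(matrix) != "beta") stop("`matrix` must be on the beta scale")
  bad <- which(!is.na(matrix) & (matrix <= 0 | matrix >= 1))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(matrix))
    stop(sprintf("beta value outside (0,1) at probe '%s', sample '%s'",
                 rownames(matrix)[rc[1]], colnames(matrix)[rc[2]]))
  }
  out <- log2(matrix / (1 - matrix))
  meth_matrix(structure(unclass(out), scale = NULL), scale = "M")
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(matrix) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (value_scale(matrix) != "M") stop("`matrix` must be on the M scale")
  out <- 2^matrix / (1 + 2^matrix)
  meth_matrix(structure(unclass(out), scale = NULL), scale = "beta")
}

#' Filter probes by call rate
#'
#' Retains exactly the probes whose fraction of non-missing values across
#' samples is at least `min_rate`. The filtering report (probes retained
#' and dropped) is attached as the `"call_rate_report"` attribute.
#'
#' @param matrix A [meth_matrix()].
#' @param min_rate Minimal non-missing fraction (default 0.95).
#' @return The filtered [meth_matrix()].
#' @export
call_rate_filter <- function(matrix, min_rate = 0.95) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (!(min_rate > 0 && min_rate <= 1)) stop("`min_rate` must be in (0, 1]")
  if (nrow(matrix) == 0 || ncol(matrix) == 0) stop("empty methylation matrix")
  rate <- rowMeans(!is.na(matrix))
  keep <- rate >= min_rate
  out <- meth_matrix(unclass(matrix)[keep, , drop = FALSE], scale = value_scale(matrix))
  attr(out, "call_rate_report") <- list(
    min_rate = min_rate, n_input = nrow(matrix),
    n_retained = sum(keep), n_dropped = sum(!keep)
  )
  out
}

#' Population mean/variance normalization
#'
#' Centers and scales every probe by the mean and (unbiased) sd of its
#' non-missing values across samples, turning the matrix into per-sample
#' residual tracks with per-probe population mean 0 and sd 1. Probes with
#' zero variance or fewer than two observations cannot be standardized and
#' are dropped with a warning. The per-probe mean/sd table is attached as
#' the `"probe_stats"` attribute.
#'
#' @param matrix A [meth_matrix()] on the M scale.
#' @return A residual-scale [meth_matrix()].
#' @export
population_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (value_scale(matrix) != "M") stop("`matrix` must be on the M scale")
  v <- unclass(matrix)
  n_obs <- rowSums(!is.na(v))
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  drop <- n_obs < 2 | is.na(sdv) | sdv == 0
  if (any(drop)) {
    warning(sprintf("dropping %d probe(s) with <2 observations or zero variance", sum(drop)))
  }
  keep <- !drop
  out <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- meth_matrix(out, scale = "residual")
  attr(out, "probe_stats") <- tibble::tibble(
    probe_id = rownames(v), n_obs = n_obs, mean = mu, sd = sdv, dropped = drop
  )
  out
}

#' Split a residual matrix into per-sample, per-chromosome tracks
#'
#' Joins the residual matrix to the probe manifest and emits one
#' [chromosome_track()] per (sample, chromosome), with missing values
#' dropped and positions sorted. Tracks with fewer than `min_sites`
#' observed sites are skipped with a warning: so few sites leave the
#' dependency hyperparameters essentially unidentifiable.
#'
#' @param matrix A residual-scale [meth_matrix()].
#' @param manifest A manifest tibble ([read_probe_manifest()]).
#' @param min_sites Minimal observed sites per track (default 50).
#' @return A tibble with columns `sample_id`, `chrom`, `n_sites`, `track`
#'   (list-column of [chromosome_track()]).
#' @export
split_by_chromosome <- function(matrix, manifest, min_sites = 50) {
  stopifnot(inherits(matrix, "meth_matrix"))
  if (value_scale(matrix) != "residual") stop("`matrix` must be population-normalized residuals")
  missing_probes <- setdiff(rownames(matrix), manifest$probe_id)
  if (length(missing_probes)) {
    stop(sprintf("%d matrix probe(s) absent from manifest, e.g. '%s'",
                 length(missing_probes), missing_probes[1]))
  }
  man <- manifest[match(rownames(matrix), manifest$probe_id), ]
  dup <- duplicated(man[c("chrom", "pos")])
  if (any(dup)) {
    stop(sprintf(paste0("duplicate (chromosome, position) in manifest at chr%d:%d; ",
                        "deduplicate probes before splitting"),
                 man$chrom[dup][1], man$pos[dup][1]))
  }
  ord <- order(man$chrom, man$pos)
  v <- unclass(matrix)[ord, , drop = FALSE]
  man <- man[ord, ]
  samples <- colnames(matrix)
  chroms <- sort(unique(man$chrom))
  rows <- list()
  n_skipped <- 0L
  for (ch in chroms) {
    sel <- man$chrom == ch
    pos_ch <- man$pos[sel]
    v_ch <- v[sel, , drop = FALSE]
    for (s in samples) {
      obs <- !is.na(v_ch[, s])
      if (sum(obs) < min_sites) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = s, chrom = ch, n_sites = sum(obs),
        track = list(chromosome_track(pos_ch[obs], v_ch[obs, s],
                                      sample_id = s, chrom = ch))
      )
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("skipped %d track(s) with fewer than %d observed sites",
                    n_skipped, min_sites))
  }
  dplyr::bind_rows(rows)
}
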