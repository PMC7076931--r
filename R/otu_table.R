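#' OTU count table with sample metadata
#'
#' Container for a samples x OTUs matrix of non-negative integer read counts
#' plus per-sample metadata (site, region, domain). Samples and OTUs are kept
#' in lexicographic order so that downstream grouping and pooling are
#' reproducible.
#'
#' @param counts integer matrix, rows = samples, columns = OTUs, with unique
#'   dimnames.
#' @param site,region character vectors, one entry per sample (recycled if
#'   length 1).
#' @param domain one of `"bacteria"`, `"eukarya"`, `"archaea"` (or
#'   `"unspecified"` when metadata are genuinely absent); per sample, recycled
#'   if length 1.
#' @param taxonomy optional named character vector of opaque taxonomy
#'   annotations, names matching OTU ids.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix), `metadata` (data.frame with `sample_id`, `site`,
#'   `region`, `domain`) and `taxonomy`.
#' @export
otu_table <- function(counts, site, region, domain, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  n <- nrow(counts)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  meta <- data.frame(sample_id = rownames(counts),
                     site = rec(as.character(site)),
                     region = rec(as.character(region)),
                     domain = rec(as.character(domain)),
                     stringsAsFactors = FALSE)
  obj <- structure(list(counts = counts, metadata = meta, taxonomy = taxonomy),
                   class = "otu_table")
  obj <- .sort_otu_table(obj)
  validate_otu_table(obj)
  obj
}

.sort_otu_table <- function(x) {
  so <- order(rownames(x$counts), method = "radix")
  oo <- order(colnames(x$counts), method = "radix")
  x$counts <- x$counts[so, oo, drop = FALSE]
  x$metadata <- x$metadata[so, , drop = FALSE]
  rownames(x$metadata) <- NULL
  if (!is.null(x$taxonomy)) x$taxonomy <- x$taxonomy[colnames(x$counts)]
  x
}

.domains <- c("bacteria", "eukarya", "archaea", "unspecified")

#' Validate an otu_table's invariants
#'
#' Checks integer non-negative counts, unique sample and OTU ids, and complete
#' site/region/domain assignment. Errors describe the offending row/column.
#'
#' @param x an `otu_table`.
#' @return `x`, invisibly, if valid.
#' @export
validate_otu_table <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  cnt <- x$counts
  if (anyDuplicated(rownames(cnt)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(cnt)[duplicated(rownames(cnt))]), collapse = ", "))
  if (anyDuplicated(colnames(cnt)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(cnt)[duplicated(colnames(cnt))]), collapse = ", "))
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("counts must be non-negative integers; first offending cell: sample '",
         rownames(cnt)[bad[1, 1]], "', OTU '", colnames(cnt)[bad[1, 2]],
         "' (value ", cnt[bad[1, 1], bad[1, 2]], ")")
  m <- x$metadata
  if (!identical(m$sample_id, rownames(cnt)))
    stop("metadata sample_id does not match count matrix rows")
  for (col in c("site", "region", "domain"))
    if (any(is.na(m[[col]]) | m[[col]] == ""))
      stop("every sample needs a ", col, " assignment")
  if (!all(m$domain %in% .domains))
    stop("domain must be one of ", paste(.domains, collapse = "|"))
  invisible(x)
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  domains:", paste(unique(x$metadata$domain), collapse = ", "), "\n")
  cat("  regions:", paste(unique(x$metadata$region), collapse = ", "),
      "| sites:", length(unique(x$metadata$site)), "\n")
  cat("  total reads:", sum(x$counts), "\n")
  invisible(x)
}

#' Subset an otu_table by samples and/or OTUs
#'
#' @param x an `otu_table`.
#' @param samples,otus character or logical/integer index vectors; `NULL`
#'   keeps everything.
#' @param drop_empty_otus drop OTUs whose counts sum to zero after subsetting.
#' @return an `otu_table`.
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL,
                             drop_empty_otus = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  cnt <- x$counts
  if (!is.null(samples)) cnt <- cnt[samples, , drop = FALSE]
  if (!is.null(otus)) cnt <- cnt[, otus, drop = FALSE]
  if (drop_empty_otus) cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
  keep <- match(rownames(cnt), x$metadata$sample_id)
  tax <- if (is.null(x$taxonomy)) NULL else x$taxonomy[colnames(cnt)]
  otu_table(cnt, x$metadata$site[keep], x$metadata$region[keep],
            x$metadata$domain[keep], taxonomy = tax)
}

#' Combine otu_tables over the union of their OTUs
#'
#' Samples are stacked; missing OTU counts are zero-filled. Used by the
#' synthetic-data generator to assemble multi-site tables.
#'
#' @param tables list of `otu_table` objects with disjoint sample ids.
#' @return an `otu_table`.
#' @export
combine_otu_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  otus <- sort(unique(unlist(lapply(tables, function(t) colnames(t$counts)))))
  rows <- lapply(tables, function(t) {
    m <- matrix(0L, nrow(t$counts), length(otus),
                dimnames = list(rownames(t$counts), otus))
    m[, colnames(t$counts)] <- t$counts
    m
  })
  cnt <- do.call(rbind, rows)
  meta <- do.call(rbind, lapply(tables, function(t) t$metadata))
  tax <- do.call(c, lapply(tables, function(t) t$taxonomy))
  if (!is.null(tax)) tax <- tax[!duplicated(names(tax))]
  otu_table(cnt, meta$site, meta$region, meta$domain, taxonomy = tax)
}

#' Read an OTU table in QIIME-classic TSV dialect
#'
#' The on-disk orientation is OTUs x samples with first header cell
#' `"#OTU ID"`; an optional trailing `taxonomy` column is preserved as an
#' opaque OTU annotation. In memory the orientation is samples x OTUs.
#'
#' @param path path to a tab-separated file.
#' @param metadata optional per-sample metadata: a data.frame with columns
#'   `sample_id`, `site`, `region`, `domain`, or a path to such a CSV. When
#'   absent all three fields are `"unspecified"`.
#' @return an `otu_table`.
#' @export
read_otu_table <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L || hdr[1] != "#OTU ID")
    stop("malformed header in ", path, ": first cell must be '#OTU ID'")
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "otu_id"
  tax <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    tax <- setNames(as.character(df[[ncol(df)]]), df$otu_id)
    df <- df[, -ncol(df), drop = FALSE]
  }
  if (anyDuplicated(df$otu_id))
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  samp <- names(df)[-1]
  if (anyDuplicated(samp))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m) | is.na(m), arr.ind = TRUE)
  if (length(m) > 0 && nrow(bad) > 0)
    stop("non-integer or negative count in ", path, " at OTU '",
         df$otu_id[bad[1, 1]], "', sample '", samp[bad[1, 2]], "'")
  storage.mode(m) <- "integer"
  rownames(m) <- df$otu_id
  cnt <- t(m)
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_sample_metadata(metadata)
  if (is.null(metadata)) {
    otu_table(cnt, "unspecified", "unspecified", "unspecified", taxonomy = tax)
  } else {
    i <- match(rownames(cnt), metadata$sample_id)
    if (anyNA(i))
      stop("metadata missing samples: ",
           paste(rownames(cnt)[is.na(i)], collapse = ", "))
    otu_table(cnt, metadata$site[i], metadata$region[i], metadata$domain[i],
              taxonomy = tax)
  }
}

#' Write an OTU table in QIIME-classic TSV dialect
#'
#' @param x an `otu_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  m <- t(x$counts)
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy[rownames(m)])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata (sample_id, site, region, domain) from CSV
#'
#' @param path CSV path with at least columns `sample_id`, `site`, `region`,
#'   `domain` (case-insensitive).
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sample_id", "site", "region", "domain")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata ", path, " missing columns: ", paste(miss, collapse = ", "))
  df[, need]
}

# canonical environmental covariate names and their accepted aliases
.env_aliases <- list(
  NO2_NO3 = c("no2", "no3", "no2/no3", "no2_no3", "no2.no3", "no2no3"),
  pH = "ph", conductivity = c("cond", "conductivity"),
  TC = c("tc", "total_carbon"), TN = c("tn", "total_nitrogen"),
  TP = c("tp", "total_phosphorous", "total_phosphorus"),
  P = "p", Cu = "cu", Al = "al", Al2O3 = c("al2o3", "al_2_o_3"),
  TiO2 = c("tio2", "tio_2"), CECCa = c("cecca", "cec_ca"),
  CECNa = c("cecna", "cec_na"), DMF = c("dmf", "dry_matter_fraction"),
  gravel = c("gravel", "grvl"), mud = "mud"
)

#' Normalize environmental covariate names through the alias map
#'
#' Case-insensitive; e.g. `NO2`, `NO3` and `NO2/NO3` all map to `NO2_NO3`
#' (the source tables are ambiguous between nitrite spellings) and the
#' substitution is reported with a message. Unrecognized names pass through
#' unchanged.
#'
#' @param nms character vector of column names.
#' @return character vector of canonical names.
#' @export
normalize_env_names <- function(nms) {
  low <- tolower(nms)
  out <- nms
  for (canon in names(.env_aliases)) {
    hit <- low %in% .env_aliases[[canon]]
    changed <- nms[hit][nms[hit] != canon]
    if (length(changed) > 0)
      message("env column alias: ", paste(changed, collapse = ", "),
              " -> ", canon)
    out[hit] <- canon
  }
  out
}

#' Read a per-sample environmental covariate table from CSV
#'
#' First column (or a column named `sample_id`) keys rows to sample ids;
#' remaining columns are numeric covariates. Column names are normalized via
#' [normalize_env_names()]. Missing values stay `NA`.
#'
#' @param path CSV path.
#' @return data.frame of numeric covariates with sample ids as row names.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  key <- if ("sample_id" %in% tolower(names(df)))
    which(tolower(names(df)) == "sample_id")[1] else 1L
  ids <- as.character(df[[key]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  df <- df[, -key, drop = FALSE]
  names(df) <- normalize_env_names(names(df))
  num <- as.data.frame(lapply(df, function(x) suppressWarnings(as.numeric(x))))
  names(num) <- names(df)
  rownames(num) <- ids
  num
}

#' Rarefy each sample to a fixed depth (subsampling without replacement)
#'
#' Each retained sample's counts become a uniform random subsample of exactly
#' `depth` reads drawn without replacement from that sample. Samples with
#' fewer than `depth` total reads are dropped with a warning.
#'
#' @param table an `otu_table`.
#' @param depth integer >= 1.
#' @param seed optional integer seed for reproducibility.
#' @return a rarefied `otu_table`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (length(depth) != 1L || !is.finite(depth) || depth < 1 ||
      depth != round(depth))
    stop("depth must be a single integer >= 1")
  .with_seed(seed, {
    cnt <- table$counts
    tot <- rowSums(cnt)
    drop <- tot < depth
    if (any(drop))
      warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
              paste(rownames(cnt)[drop], collapse = ", "))
    keep <- which(!drop)
    if (length(keep) == 0L) stop("no sample reaches depth ", depth)
    out <- cnt[keep, , drop = FALSE]
    for (i in seq_along(keep)) {
      r <- out[i, ]
      if (sum(r) == depth) next
      reads <- rep.int(seq_along(r), r)
      sub <- reads[sample.int(length(reads), depth)]
      out[i, ] <- tabulate(sub, nbins = length(r))
    }
    md <- table$metadata[keep, ]
    otu_table(out, md$site, md$region, md$domain, taxonomy = table$taxonomy)
  })
}

#' Filter OTUs by total relative abundance
#'
#' Keeps OTUs whose summed count exceeds `threshold_pct` percent of the grand
#' total of the supplied table (strict `>`). The caller pre-splits by region
#' and/or domain when the filter is meant within such a stratum.
#'
#' @param table an `otu_table`.
#' @param threshold_pct percentage threshold, default 0.001 (i.e. >0.001%).
#' @return filtered `otu_table`.
#' @export
filter_rel_abundance <- function(table, threshold_pct = 0.001) {
  stopifnot(inherits(table, "otu_table"))
  if (threshold_pct < 0) stop("threshold_pct must be >= 0")
  total <- sum(table$counts)
  if (nrow(table$counts) == 0L || ncol(table$counts) == 0L || total == 0)
    stop("cannot filter an empty table")
  keep <- 100 * colSums(table$counts) / total > threshold_pct
  keep <- keep & colSums(table$counts) > 0
  subset_otu_table(table, otus = which(keep))
}

#' Construct an abundance vector (pooled per-OTU counts for one group)
#'
#' @param counts named integer vector of strictly positive per-OTU counts.
#' @param group group label (e.g. a site or region name).
#' @param group_by what the label refers to (`"site"`, `"region"`, ...).
#' @param domain optional domain label.
#' @return an `abundance_vector` (named integer vector with attributes).
#' @export
abundance_vector <- function(counts, group = "group", group_by = "group",
                             domain = NULL) {
  if (length(counts) == 0L) stop("empty abundance vector")
  if (any(!is.finite(counts) | counts < 1 | counts != round(counts)))
    stop("abundance vector entries must be integers >= 1")
  structure(as.integer(round(counts)), names = names(counts),
            group = group, group_by = group_by, domain = domain,
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("abundance_vector:", length(x), "species, group =",
      attr(x, "group"), "(", attr(x, "group_by"), ")\n")
  invisible(x)
}

#' Pool per-OTU abundances within groups of samples
#'
#' Sums counts across the samples of each group (site or region); OTUs with a
#' zero group total are excluded. Groups are returned in lexicographic order.
#'
#' @param table an `otu_table`.
#' @param group_by `"site"` or `"region"`.
#' @return named list of [abundance_vector()] objects.
#' @export
pool_abundances <- function(table, group_by = c("site", "region")) {
  stopifnot(inherits(table, "otu_table"))
  group_by <- match.arg(group_by)
  g <- table$metadata[[group_by]]
  groups <- sort(unique(g))
  out <- lapply(groups, function(lab) {
    v <- colSums(table$counts[g == lab, , drop = FALSE])
    v <- v[v > 0]
    dom <- unique(table$metadata$domain[g == lab])
    abundance_vector(v, group = lab, group_by = group_by,
                     domain = if (length(dom) == 1L) dom else NULL)
  })
  names(out) <- groups
  out
}

#' Serialize a result object to TSV or JSON
#'
#' Data frames go to TSV (one header row) or JSON records; lists go to JSON.
#' Networks have their own writer, [write_network()].
#'
#' @param obj data.frame or list.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    if (!is.data.frame(obj)) stop("TSV output requires a data.frame")
    write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}
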