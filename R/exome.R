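#' Construct an exome profile
#'
#' An exome profile holds the annotated variants observed in one individual's
#' exome: a data frame with columns `variant_id`, `gene`, `zygosity`
#' ("heterozygous"/"homozygous"), and one column per ranking criterion.
#'
#' @param sample_id Sample identifier (unique within a study).
#' @param variants Data frame of variants; may have zero rows. Required
#'   columns: `variant_id`, `gene`, `zygosity`. Criterion columns are taken
#'   at face value; empty strings are treated as missing.
#' @param role `"case"` or `"control"`.
#' @return An object of class `"exome_profile"`.
#' @export
exome_profile <- function(sample_id, variants, role = c("case", "control")) {
  role <- match.arg(role)
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (missing(variants) || is.null(variants))
    variants <- data.frame(variant_id = character(), gene = character(),
                           zygosity = character(), stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "zygosity")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table for '", sample_id, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  variants$gene <- trimws(as.character(variants$gene))
  if (nrow(variants) && any(!nzchar(variants$gene)))
    stop("variant table for '", sample_id, "' has empty gene symbols")
  variants$zygosity <- normalize_zygosity(variants$zygosity)
  variants$variant_id <- as.character(variants$variant_id)
  rownames(variants) <- NULL
  structure(list(sample_id = sample_id, role = role, variants = variants),
            class = "exome_profile")
}

#' @export
print.exome_profile <- function(x, ...) {
  cat("<exome>", x$sample_id, "(", x$role, "):", nrow(x$variants),
      "variants in", length(unique(x$variants$gene)), "genes\n")
  invisible(x)
}

# Fixed alias table for zygosity labels (VCF-style genotypes included).
.zygosity_aliases <- c(
  heterozygous = "heterozygous", het = "heterozygous", "0/1" = "heterozygous",
  "0|1" = "heterozygous", "1/0" = "heterozygous", "1|0" = "heterozygous",
  homozygous = "homozygous", hom = "homozygous", "1/1" = "homozygous",
  "1|1" = "homozygous")

#' Normalize zygosity labels
#'
#' Maps the fixed alias table ("het", "hom", "0/1", "1/1", ...) onto the two
#' canonical labels `"heterozygous"` and `"homozygous"`.
#'
#' @param x Character vector of zygosity labels.
#' @return Character vector of canonical labels.
#' @export
normalize_zygosity <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- unname(.zygosity_aliases[x])
  if (anyNA(out) && length(x))
    stop("unknown zygosity label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read an annotated variant table
#'
#' Reads a tab-separated table with header columns `sample`, `gene`,
#' `zygosity`, `variant_id` plus one column per criterion name. Empty cells
#' denote missing annotations. Extra columns are ignored. One file may hold
#' several samples; one [exome_profile()] is returned per sample.
#'
#' @param path Path to the TSV file.
#' @param criteria List of [criterion()] objects; category labels in the
#'   table are validated against each ordered criterion's declared order.
#' @param role Role assigned to all profiles read (`"case"` or `"control"`).
#' @return A named list of [exome_profile()] objects (single element if the
#'   file holds one sample).
#' @export
read_variant_table <- function(path, criteria, role = c("case", "control")) {
  role <- match.arg(role)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  need <- c("sample", "gene", "zygosity", "variant_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("'", path, "': missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  cnames <- criteria_names(criteria)
  miss <- setdiff(cnames, names(tab))
  if (length(miss))
    stop("'", path, "': missing criterion column(s): ",
         paste(miss, collapse = ", "))
  # validate categorical labels up front so errors carry row numbers
  for (cr in criteria)
    if (cr$kind == "ordered_categories") criterion_key(tab[[cr$name]], cr)
  keep <- c("variant_id", "gene", "zygosity", cnames)
  samples <- if (nrow(tab)) unique(tab$sample) else character()
  out <- lapply(samples, function(s)
    exome_profile(s, tab[tab$sample == s, keep, drop = FALSE], role = role))
  names(out) <- samples
  if (!nrow(tab)) {
    # header-only file: a single empty profile named after the file
    sid <- sub("\\.[^.]*$", "", basename(path))
    out <- stats::setNames(list(exome_profile(sid, NULL, role = role)), sid)
  }
  out
}

#' Write exome profiles as an annotated variant table
#'
#' Inverse of [read_variant_table()]: writes one long TSV with a `sample`
#' column. Missing annotations become empty cells.
#'
#' @param profiles A single [exome_profile()] or a list of them.
#' @param path Output TSV path.
#' @param criteria List of [criterion()] objects defining the columns written.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(profiles, path, criteria) {
  if (inherits(profiles, "exome_profile")) profiles <- list(profiles)
  cnames <- criteria_names(criteria)
  rows <- lapply(profiles, function(p) {
    v <- p$variants
    if (!nrow(v))
      return(NULL)
    df <- data.frame(sample = p$sample_id, gene = v$gene,
                     zygosity = v$zygosity, variant_id = v$variant_id,
                     stringsAsFactors = FALSE)
    for (nm in cnames)
      df[[nm]] <- if (nm %in% names(v)) as.character(v[[nm]]) else ""
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(), gene = character(),
                      zygosity = character(), variant_id = character())
  out[is.na(out)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read every variant table in a directory
#'
#' @param dir Directory containing `.tsv` variant tables.
#' @param criteria List of [criterion()] objects.
#' @param role Role for all profiles read.
#' @return Named list of [exome_profile()] objects, merged across files.
#' @export
read_study_dir <- function(dir, criteria, role = c("case", "control")) {
  role <- match.arg(role)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv variant tables found in '", dir, "'")
  out <- list()
  for (f in files) out <- c(out, read_variant_table(f, criteria, role = role))
  if (anyDuplicated(names(out)))
    stop("duplicate sample ids across files in '", dir, "'")
  out
}

#' Import case profiles from an annotated VCF
#'
#' Convenience adapter for VCF v4.x files whose INFO field carries the gene
#' symbol and criterion annotations. Genotypes are taken from the first
#' sample column (`0/1`-style) when present, else from an INFO key.
#'
#' @param path Path to an uncompressed VCF file.
#' @param criteria List of [criterion()] objects; each criterion's annotation
#'   is read from the INFO key of the same name (mapped via `info_keys`).
#' @param info_keys Named character vector mapping the table's column names
#'   (`gene` plus criterion names) to INFO keys; defaults to identity with
#'   `gene = "GENE"`.
#' @param sample_id Sample identifier; defaults to the VCF sample name or the
#'   file name.
#' @param role `"case"` or `"control"`.
#' @return A single [exome_profile()].
#' @export
read_vcf_profile <- function(path, criteria,
                             info_keys = c(gene = "GENE"),
                             sample_id = NULL, role = c("case", "control")) {
  role <- match.arg(role)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  cols <- if (length(hdr)) strsplit(hdr[1], "\t", fixed = TRUE)[[1]] else character()
  if (is.null(sample_id))
    sample_id <- if (length(cols) >= 10) cols[10] else
      sub("\\.[^.]*$", "", basename(path))
  cnames <- criteria_names(criteria)
  keys <- stats::setNames(c("GENE", cnames), c("gene", cnames))
  keys[names(info_keys)] <- info_keys
  parse_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  rows <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF record: ", substr(ln, 1, 60))
    gt <- if (length(f) >= 10) sub(":.*", "", f[10]) else NA_character_
    zyg <- if (!is.na(gt) && gt %in% names(.zygosity_aliases)) gt else "het"
    rec <- list(variant_id = paste0(f[1], ":", f[2], "_", f[4], ">", f[5]),
                gene = parse_info(f[8], keys[["gene"]]), zygosity = zyg)
    for (nm in cnames) rec[[nm]] <- parse_info(f[8], keys[[nm]])
    rec
  })
  v <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(v)) v <- NULL
  exome_profile(sample_id, v, role = role)
}
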