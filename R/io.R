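#' Read a protein domain annotation table
#'
#' Parses per-protein domain hits from either an `hmmscan --domtblout`
#' file or a generic five-column TSV, and filters hits by E-value.
#'
#' The generic TSV dialect expects a header line with (at least) the
#' columns `protein_id`, `domain_name`, `env_start`, `env_end`,
#' `e_value`. The hmmscan dialect parses the standard whitespace-separated
#' domain table: the target (HMM) name becomes `domain_name`, the query
#' name becomes `protein_id`, the independent per-domain E-value
#' (i-Evalue) becomes `e_value`, and the envelope coordinates give
#' `env_start`/`env_end`. Envelope coordinates are used, rather than
#' alignment coordinates, because the envelope is the standard estimate
#' of the full domain extent.
#'
#' @param path Path to the annotation file.
#' @param dialect Either `"generic_tsv"` or `"hmmscan_domtbl"`.
#' @param max_evalue Keep hits with `e_value <= max_evalue` (inclusive,
#'   following common practice for E-value cutoffs). Default `Inf`.
#' @return A data frame with columns `protein_id`, `domain_name`,
#'   `env_start`, `env_end`, `e_value`, rows in file order.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\tdomain_name\tenv_start\tenv_end\te_value",
#'              "p1\tNB-ARC\t10\t300\t1e-30",
#'              "p1\tLRR\t350\t500\t1e-5"), tsv)
#' read_domain_table(tsv, "generic_tsv")
#' @export
read_domain_table <- function(path, dialect = c("generic_tsv", "hmmscan_domtbl"),
                              max_evalue = Inf) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(dialect) == 1L && !dialect %in% c("generic_tsv", "hmmscan_domtbl"))
    stop("unknown dialect: ", dialect)
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines)
  idx <- which(keep & nzchar(trimws(lines)))

  if (dialect == "generic_tsv") {
    if (length(idx) == 0L) return(empty_domain_table())
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    header <- fields[[1L]]
    need <- c("protein_id", "domain_name", "env_start", "env_end", "e_value")
    pos <- match(need, header)
    if (anyNA(pos))
      stop("generic_tsv header must contain columns: ",
           paste(need[is.na(pos)], collapse = ", "))
    rows <- fields[-1L]
    lnos <- idx[-1L]
    if (length(rows) == 0L) return(empty_domain_table())
    bad <- which(vapply(rows, length, 1L) < length(header))
    if (length(bad))
      stop("unparseable row at line ", lnos[bad[1L]], " of ", path)
    get <- function(j) vapply(rows, `[[`, "", j)
    hit <- data.frame(
      protein_id  = get(pos[1L]),
      domain_name = get(pos[2L]),
      env_start   = suppressWarnings(as.integer(get(pos[3L]))),
      env_end     = suppressWarnings(as.integer(get(pos[4L]))),
      e_value     = suppressWarnings(as.numeric(get(pos[5L]))),
      stringsAsFactors = FALSE
    )
    bad <- which(is.na(hit$env_start) | is.na(hit$env_end) | is.na(hit$e_value))
    if (length(bad))
      stop("unparseable row at line ", lnos[bad[1L]], " of ", path)
  } else {
    if (length(idx) == 0L) return(empty_domain_table())
    fields <- strsplit(trimws(lines[idx]), "[[:space:]]+")
    bad <- which(vapply(fields, length, 1L) < 22L)
    if (length(bad))
      stop("unparseable row at line ", idx[bad[1L]], " of ", path,
           " (expected >= 22 whitespace-separated fields)")
    get <- function(j) vapply(fields, `[[`, "", j)
    hit <- data.frame(
      protein_id  = get(4L),
      domain_name = get(1L),
      env_start   = suppressWarnings(as.integer(get(20L))),
      env_end     = suppressWarnings(as.integer(get(21L))),
      e_value     = suppressWarnings(as.numeric(get(13L))),
      stringsAsFactors = FALSE
    )
    bad <- which(is.na(hit$env_start) | is.na(hit$env_end) | is.na(hit$e_value))
    if (length(bad))
      stop("unparseable row at line ", idx[bad[1L]], " of ", path)
  }
  if (any(hit$env_start < 1L) || any(hit$env_end < hit$env_start))
    stop("invalid envelope coordinates (need 1 <= env_start <= env_end)")
  if (any(hit$e_value < 0)) stop("negative E-value in ", path)
  hit[hit$e_value <= max_evalue, , drop = FALSE]
}

empty_domain_table <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             env_start = integer(), env_end = integer(),
             e_value = numeric(), stringsAsFactors = FALSE)
}

#' Read query identifiers from a tabular BLAST report
#'
#' Reads a 12-column tabular BLAST file (`-outfmt 6` layout) and returns
#' the distinct query identifiers having at least one hit at or below the
#' E-value cutoff. The conventional cutoff for homology screening of NLR
#' candidates is 1e-3.
#'
#' @param path Path to the BLAST tabular file.
#' @param max_evalue E-value cutoff (inclusive); must be positive.
#' @return Character vector of distinct query ids, in order of first
#'   qualifying appearance.
#' @export
read_blast_hits <- function(path, max_evalue = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.numeric(max_evalue), max_evalue > 0)
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(idx) == 0L) return(character())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns at line ", idx[which(nf != 12L)[1L]],
         " of ", path, " (found ", nf[which(nf != 12L)[1L]], ")")
  qid <- vapply(fields, `[[`, "", 1L)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (anyNA(ev))
    stop("unparseable E-value at line ", idx[which(is.na(ev))[1L]], " of ", path)
  if (any(ev < 0)) stop("negative E-value in ", path)
  unique(qid[ev <= max_evalue])
}

#' Read a rooted newick gene tree
#'
#' Reads a single newick tree, preserving leaf labels verbatim, branch
#' lengths, and internal-node support labels. The tree is treated as
#' rooted exactly as written; no re-rooting is performed. Duplicate leaf
#' labels are an error because downstream event calling requires unique
#' gene identifiers.
#'
#' @param path Path to a newick file containing one tree ending in `;`.
#' @return An [ape::phylo] object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(trimws(readLines(path, warn = FALSE)), collapse = "")
  if (!nzchar(txt) || !endsWith(txt, ";"))
    stop("newick parse error: tree must end with ';' in ", path)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("newick parse error: unbalanced parentheses in ", path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("newick parse error in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Write uniform records as a CSV table
#'
#' Writes a data frame (or list of uniform named records) to CSV with a
#' header row and a deterministic field order (the order of the first
#' record). Output uses '.' as the decimal separator, UTF-8 encoding and
#' LF line endings; fields containing commas or quotes are quoted per the
#' CSV standard, so a read-back recovers the input values.
#'
#' @param records A data frame, or a list of named lists sharing the same
#'   field names.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L) stop("cannot infer fields from an empty record list; pass a data frame")
    nms <- names(records[[1L]])
    if (is.null(nms) || any(!nzchar(nms))) stop("records must have named fields")
    ok <- vapply(records, function(r) identical(sort(names(r)), sort(nms)), TRUE)
    if (!all(ok)) stop("heterogeneous records: field names differ at record ",
                       which(!ok)[1L])
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r[nms], stringsAsFactors = FALSE)))
  } else stop("records must be a data frame or list of named records")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(df)
}

#' Read a FASTA alignment as a character matrix
#'
#' @param path Path to an aligned FASTA file (equal-length sequences).
#' @return Character matrix, rows named by sequence id, entries upper-case
#'   single characters from `{A,C,G,T,-,N,...}`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aln <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  if (is.null(dim(aln))) stop("sequences are not aligned (unequal lengths)")
  m <- toupper(unclass(aln))
  if (nrow(m) < 2L) stop("alignment must contain at least 2 sequences")
  m
}

#' Read a two-column gene-to-species map
#'
#' @param path TSV with two columns: gene id, species id. A header line
#'   `gene_id<TAB>species_id` is permitted and skipped.
#' @return Named character vector mapping gene id to species id.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "species_id"))
  if (nrow(df) && df$gene_id[1L] == "gene_id") df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in species map")
  stats::setNames(df$species_id, df$gene_id)
}
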