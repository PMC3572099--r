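#' Normalize a protein accession
#'
#' Uppercases, strips surrounding whitespace, and removes a trailing isoform
#' suffix (`-N`), so that protein isoforms map onto a single gene-product
#' record with one UniProt-style accession. Idempotent.
#'
#' @param raw_id Character vector of raw identifiers; empty strings are an error.
#' @return Character vector of normalized accessions.
#' @export
#' @examples
#' normalize_accession("p62258-2")  # "P62258"
normalize_accession <- function(raw_id) {
  if (length(raw_id) == 0L) return(character(0))
  x <- trimws(as.character(raw_id))
  if (any(is.na(x)) || any(!nzchar(x)))
    stop("malformed identifier: empty accession")
  x <- toupper(x)
  sub("-[0-9]+$", "", x)
}

read_table_checked <- function(path, required, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read an interaction table
#'
#' Tab- (or comma-) separated pair list with columns `id_a`, `id_b` and an
#' optional `source`. Accessions are normalized, self-interactions dropped
#' (14-3-3 dimerization is deliberately excluded from the comparison), and
#' undirected duplicates collapsed so at most one edge remains per unordered
#' pair. GraphML input is delegated to [read_network()].
#'
#' @param path Input file.
#' @param format `"tsv"` (also covers CSV) or `"graphml"`.
#' @param keep_self Keep self-interactions (default FALSE).
#' @return A data.frame of interactions (`id_a`, `id_b`, `source`) with
#'   attribute `rejects`: a data.frame of unparseable rows and reasons.
#' @export
read_interactions <- function(path, format = c("tsv", "graphml"),
                              keep_self = FALSE) {
  format <- match.arg(format)
  if (format == "graphml") {
    net <- read_network(path)
    return(net$edges)
  }
  df <- read_table_checked(path, c("id_a", "id_b"))
  if (!"source" %in% names(df)) df$source <- rep(NA_character_, nrow(df))
  rejects <- data.frame(row = integer(0), reason = character(0))
  ok_id <- function(x) !is.na(x) & nzchar(trimws(as.character(x)))
  bad <- !(ok_id(df$id_a) & ok_id(df$id_b))
  if (any(bad)) {
    rejects <- data.frame(row = which(bad), reason = "missing identifier")
    df <- df[!bad, , drop = FALSE]
  }
  edges <- normalize_edges(
    data.frame(id_a = normalize_accession(df$id_a),
               id_b = normalize_accession(df$id_b),
               source = as.character(df$source),
               stringsAsFactors = FALSE),
    keep_self = keep_self)
  attr(edges, "rejects") <- rejects
  edges
}

# canonical undirected edge table: id_a < id_b lexicographically, deduplicated,
# sorted; row order of the input never matters.
normalize_edges <- function(edges, keep_self = FALSE) {
  if (nrow(edges) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  swap <- edges$id_a > edges$id_b
  tmp <- edges$id_a[swap]
  edges$id_a[swap] <- edges$id_b[swap]
  edges$id_b[swap] <- tmp
  if (!keep_self) edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
  key <- paste(edges$id_a, edges$id_b, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Read a PTM site table
#'
#' Columns `protein_id`, `position` (1-based), `residue` (one-letter code),
#' `modification`. Rows whose residue is incompatible with the modification
#' (phosphorylation off S/T/Y, acetylation off K) or whose position is not a
#' positive integer are rejected, counted, and reported — the downstream
#' composition analysis pivots on residue identity, so such rows are data
#' errors rather than noise. Duplicate (protein, position, modification) rows
#' collapse to one site.
#'
#' @param path Input file.
#' @return data.frame of sites with attribute `rejects` (row, reason).
#' @export
read_ptm_table <- function(path) {
  df <- read_table_checked(path, c("protein_id", "position", "residue",
                                   "modification"))
  validate_ptm_sites(df)
}

#' Validate an in-memory PTM site table
#'
#' Applies the residue/modification compatibility and coordinate rules of
#' [read_ptm_table()] to a data.frame.
#'
#' @param df data.frame with columns `protein_id`, `position`, `residue`,
#'   `modification`.
#' @return Validated, deduplicated site table with attribute `rejects`.
#' @export
validate_ptm_sites <- function(df) {
  n <- nrow(df)
  pos <- suppressWarnings(as.numeric(df$position))
  residue <- toupper(trimws(as.character(df$residue)))
  modif <- tolower(trimws(as.character(df$modification)))
  reason <- rep(NA_character_, n)
  bad_pos <- is.na(pos) | pos < 1 | pos != round(pos)
  reason[bad_pos] <- "position not a positive integer"
  bad_phos <- modif == "phosphorylation" & !residue %in% c("S", "T", "Y")
  reason[is.na(reason) & bad_phos] <- "phosphorylation on non-S/T/Y residue"
  bad_ac <- modif == "acetylation" & residue != "K"
  reason[is.na(reason) & bad_ac] <- "acetylation on non-K residue"
  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(rejects) > 0L)
    warning(nrow(rejects), " PTM row(s) rejected (see attr 'rejects')")
  out <- data.frame(protein_id = normalize_accession(df$protein_id[keep]),
                    position = as.integer(pos[keep]),
                    residue = residue[keep],
                    modification = modif[keep],
                    stringsAsFactors = FALSE)
  key <- paste(out$protein_id, out$position, out$modification, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$protein_id, out$position, out$modification), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Read the per-protein annotation tables into one bundle
#'
#' All paths are optional; absent files yield empty tables. Coordinates are
#' 1-based inclusive throughout. Overlapping or adjacent disorder segments of
#' one protein are merged at load.
#'
#' @param domain_path,disorder_path,go_path,localization_path,kinase_group_path,clade_path
#'   Paths to the respective TSV tables (see the package README for schemas),
#'   or NULL.
#' @return List of data.frames: `domains`, `disorder`, `go`, `localization`,
#'   `kinase_groups`, `clades`; attribute `log` records merges/rejections.
#' @export
read_annotation_tables <- function(domain_path = NULL, disorder_path = NULL,
                                   go_path = NULL, localization_path = NULL,
                                   kinase_group_path = NULL, clade_path = NULL) {
  log <- character(0)
  domains <- empty_domains()
  if (!is.null(domain_path)) {
    df <- read_table_checked(domain_path,
                             c("protein_id", "domain_name", "start", "end"))
    domains <- data.frame(protein_id = normalize_accession(df$protein_id),
                          domain_name = as.character(df$domain_name),
                          start = as.integer(df$start),
                          end = as.integer(df$end),
                          stringsAsFactors = FALSE)
    bad <- domains$start < 1L | domains$end < domains$start
    if (any(bad)) {
      log <- c(log, sprintf("domains: %d row(s) with invalid coordinates dropped",
                            sum(bad)))
      domains <- domains[!bad, , drop = FALSE]
    }
  }
  disorder <- empty_segments()
  if (!is.null(disorder_path)) {
    df <- read_table_checked(disorder_path, c("protein_id", "start", "end"))
    seg <- data.frame(protein_id = normalize_accession(df$protein_id),
                      start = as.integer(df$start),
                      end = as.integer(df$end), stringsAsFactors = FALSE)
    merged <- merge_segments(seg)
    if (nrow(merged) < nrow(seg))
      log <- c(log, sprintf("disorder: %d overlapping segment(s) merged",
                            nrow(seg) - nrow(merged)))
    disorder <- merged
  }
  go <- data.frame(protein_id = character(0), term_id = character(0))
  if (!is.null(go_path)) {
    df <- read_table_checked(go_path, c("protein_id", "term_id"))
    go <- unique(data.frame(protein_id = normalize_accession(df$protein_id),
                            term_id = as.character(df$term_id),
                            stringsAsFactors = FALSE))
  }
  localization <- data.frame(protein_id = character(0), label = character(0))
  if (!is.null(localization_path)) {
    df <- read_table_checked(localization_path, c("protein_id", "label"))
    localization <- unique(data.frame(
      protein_id = normalize_accession(df$protein_id),
      label = as.character(df$label), stringsAsFactors = FALSE))
  }
  kinase_groups <- data.frame(protein_id = character(0), group = character(0))
  if (!is.null(kinase_group_path)) {
    df <- read_table_checked(kinase_group_path, c("protein_id", "group"))
    kinase_groups <- unique(data.frame(
      protein_id = normalize_accession(df$protein_id),
      group = as.character(df$group), stringsAsFactors = FALSE))
  }
  clades <- data.frame(protein_id = character(0), clade_id = integer(0))
  if (!is.null(clade_path)) {
    df <- read_table_checked(clade_path, c("protein_id", "clade_id"))
    cl <- suppressWarnings(as.integer(df$clade_id))
    bad <- is.na(cl) | cl < 1L | cl > 1250L
    if (any(bad))
      log <- c(log, sprintf("clades: %d row(s) with clade id outside 1-1250 rejected",
                            sum(bad)))
    clades <- unique(data.frame(
      protein_id = normalize_accession(df$protein_id[!bad]),
      clade_id = cl[!bad], stringsAsFactors = FALSE))
  }
  out <- list(domains = domains, disorder = disorder, go = go,
              localization = localization, kinase_groups = kinase_groups,
              clades = clades)
  attr(out, "log") <- log
  out
}

empty_domains <- function()
  data.frame(protein_id = character(0), domain_name = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)

empty_segments <- function()
  data.frame(protein_id = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)

# merge overlapping/adjacent 1-based inclusive segments per protein
merge_segments <- function(seg) {
  if (nrow(seg) == 0L) return(seg)
  seg <- seg[order(seg$protein_id, seg$start, seg$end), , drop = FALSE]
  out <- do.call(rbind, lapply(split(seg, seg$protein_id), function(s) {
    st <- s$start; en <- s$end
    keep_st <- st[1]; keep_en <- en[1]; res <- NULL
    if (nrow(s) > 1L) {
      for (i in 2:nrow(s)) {
        if (st[i] <= keep_en + 1L) {
          keep_en <- max(keep_en, en[i])
        } else {
          res <- rbind(res, c(keep_st, keep_en))
          keep_st <- st[i]; keep_en <- en[i]
        }
      }
    }
    res <- rbind(res, c(keep_st, keep_en))
    data.frame(protein_id = s$protein_id[1], start = res[, 1], end = res[, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
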