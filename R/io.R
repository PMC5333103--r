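#' Read a weighted gene network from a STRING-style edge list
#'
#' Reads a whitespace- or tab-delimited file with at least three columns
#' (gene A, gene B, integer confidence score) such as STRING
#' `protein.links` files. A single header line is auto-detected when its
#' third field is not numeric. The edge list is canonicalized (see
#' [gene_network()]): self-loops dropped, duplicate pairs merged to the
#' maximum score.
#'
#' @param path path to the edge-list file.
#' @param min_score keep only edges with confidence `S >= min_score`.
#'   Default 1 keeps every edge. The STRING confidence tiers are the usual
#'   presets: 150 (low), 400 (medium), 700 (high), 900 (highest).
#' @return a [gene_network()]. Gene order is first-appearance order in the
#'   file (before threshold filtering edges, after dropping self-loops).
#' @examples
#' f <- tempfile()
#' writeLines(c("g1 g2 800", "g2 g3 100"), f)
#' load_network(f, min_score = 150)  # keeps only the g1-g2 edge
#' @export
load_network <- function(path, min_score = 1L) {
  if (!file.exists(path)) {
    stop_data("network file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_data("empty network file: ", path)
  fields <- data.table::tstrsplit(trimws(lines), "[ \t]+")
  if (length(fields) < 3L) {
    stop_data("parse error at line 1: expected >= 3 fields, found ",
              length(fields))
  }
  from <- fields[[1L]]
  to <- fields[[2L]]
  raw_score <- fields[[3L]]
  offset <- 0L
  if (suppressWarnings(is.na(as.numeric(raw_score[1L])))) {
    # header line
    from <- from[-1L]
    to <- to[-1L]
    raw_score <- raw_score[-1L]
    offset <- 1L
    if (length(from) == 0L) {
      stop_data("empty network file (header only): ", path)
    }
  }
  bad <- is.na(from) | is.na(to) | is.na(raw_score) |
    from == "" | to == "" | !grepl("^[0-9]+$", raw_score)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_data("parse error at line ", i + offset,
              ": expected 'geneA geneB integer_score', got '",
              lines[i + offset], "'")
  }
  score <- as.integer(raw_score)
  out_of_range <- score <= 0L | score > 1000L
  if (any(out_of_range)) {
    line <- which(out_of_range)[1L] + offset
    stop_data("parse error at line ", line, ": confidence score ",
              score[which(out_of_range)[1L]], " outside (0, 1000]")
  }
  # gene order = first appearance in the file; self-loop and sub-threshold
  # rows still contribute their endpoints to the gene list
  genes <- unique(c(rbind(from, to)))
  keep <- score >= min_score
  net <- gene_network(
    data.frame(from = from[keep], to = to[keep], score = score[keep],
               stringsAsFactors = FALSE),
    genes = genes
  )
  net
}

#' Read disease gene sets and intersect them with a network
#'
#' Accepts either a two-column TSV (`disease_id`, `gene_id`; one association
#' per line) or GMT-style lines (`disease_id`, description, then one gene per
#' field). Gene sets are intersected with the network; diseases retaining
#' fewer than `min_size` genes are dropped with a warning. The default
#' `min_size = 2` reflects the requirement that a disease have at least two
#' known associated genes for relative-distance scoring to be meaningful.
#'
#' @param path path to the gene-set file.
#' @param network a [gene_network()] whose genes define the universe.
#' @param min_size minimum surviving set size (default 2).
#' @return named list of [disease_gene_set()] objects, in order of first
#'   appearance of each disease id.
#' @export
load_gene_sets <- function(path, network, min_size = 2L) {
  if (!file.exists(path)) stop_data("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_data("empty gene-set file: ", path)
  # tab-delimited when tabs are present (GMT descriptions may hold spaces)
  sep <- if (any(grepl("\t", lines))) "\t" else "[ ]+"
  fields <- strsplit(lines, sep)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop_data("parse error at line ", which(nf < 2L)[1L],
              ": expected at least 2 fields")
  }
  if (all(nf == 2L)) {                     # two-column TSV
    disease <- vapply(fields, `[[`, "", 1L)
    gene <- vapply(fields, `[[`, "", 2L)
    ids <- unique(disease)
    sets <- lapply(ids, function(d) {
      disease_gene_set(d, gene[disease == d])
    })
  } else if (all(nf >= 3L)) {              # GMT: id, description, genes...
    sets <- lapply(fields, function(f) {
      disease_gene_set(f[[1L]], f[-(1:2)])
    })
    ids <- vapply(sets, function(s) s$disease_id, "")
    if (anyDuplicated(ids)) {
      stop_data("duplicate disease id in GMT file: ",
                ids[duplicated(ids)][1L])
    }
  } else {
    stop_data("mixed 2-column and GMT lines; use one format per file")
  }
  sets <- lapply(sets, intersect_with_network, network = network)
  sizes <- vapply(sets, function(s) length(s$genes), 1L)
  small <- sizes < min_size
  if (any(small)) {
    warning(sprintf("%d disease(s) with fewer than %d genes in the network dropped: %s",
                    sum(small), min_size,
                    paste(vapply(sets[small], function(s) s$disease_id, ""),
                          collapse = ", ")))
    sets <- sets[!small]
  }
  if (length(sets) == 0L) {
    stop_data("no disease retained >= ", min_size, " genes in the network")
  }
  names(sets) <- vapply(sets, function(s) s$disease_id, "")
  sets
}

#' Write / read a ranked gene table
#'
#' The on-disk format is a TSV with header
#' `rank  gene  weight  score  is_known  unranked`; floats are written with
#' six decimal places. `read_ranking(write_ranking(x, f))` reproduces the
#' table exactly for the string/integer/logical columns and to 1e-6 for the
#' float columns.
#'
#' @param ranking a data frame as returned by [prioritize_disease()].
#' @param path output path.
#' @return `write_ranking` invisibly returns `path`; `read_ranking` returns
#'   the data frame.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(is.data.frame(ranking))
  need <- c("rank", "gene", "weight", "score", "is_known", "unranked")
  missing <- setdiff(need, names(ranking))
  if (length(missing) > 0L) {
    stop("ranking is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- ranking[, need, drop = FALSE]
  for (col in c("weight", "score")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.6f", out[[col]]))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_data("cannot write '", path, "': ",
                                                conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop_data("ranking file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "numeric",
                                         "numeric", "logical", "logical"),
                          na.strings = "NA", stringsAsFactors = FALSE)
  df
}

#' Read a table of GWAS SNPs
#'
#' Three-column whitespace/tab-delimited file: SNP id, host gene id,
#' association p-value. A SNP mapping to several host genes appears once per
#' gene. A header line is auto-detected (non-numeric third field).
#'
#' @param path path to the SNP table.
#' @return data frame with columns `snp_id`, `host_gene`, `p_value`.
#' @export
load_snps <- function(path) {
  if (!file.exists(path)) stop_data("SNP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(snp_id = character(), host_gene = character(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][3L])))) {
    fields <- fields[-1L]
  }
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_data("parse error in SNP table at line ", which(nf < 3L)[1L],
              ": expected 3 fields")
  }
  p <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    stop_data("parse error in SNP table at line ", which(bad)[1L],
              ": p-value must be in (0, 1]")
  }
  data.frame(snp_id = vapply(fields, `[[`, "", 1L),
             host_gene = vapply(fields, `[[`, "", 2L),
             p_value = p, stringsAsFactors = FALSE)
}

# condition helpers: data/parse problems get their own class so the CLI can
# map them to exit code 2
stop_data <- function(...) {
  stop(structure(class = c("netprio_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

stop_usage <- function(...) {
  stop(structure(class = c("netprio_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
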