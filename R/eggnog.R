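# eggNOG-mapper output parsing and FASTA annotation merging. Orthology is
# never re-scored here: whatever passed the mapper's thresholds is taken as
# given, and entries are only categorized and merged into headers.

.EMAPPER_DIALECTS <- list(
  # emapper v2.1 layout: 21 tab-separated columns
  v2 = list(ncol = 21L, query = 1L, seed_ortholog = 2L, evalue = 3L,
            gene = 9L, description = 8L),
  # 2019 web-service layout: 13 columns, predicted gene name in column 5
  v1 = list(ncol = 13L, query = 1L, seed_ortholog = 2L, evalue = 3L,
            gene = 5L, description = 13L)
)

.resolve_dialect <- function(dialect) {
  if (is.character(dialect)) {
    if (!dialect %in% names(.EMAPPER_DIALECTS)) {
      abort(sprintf(
        "unknown emapper dialect '%s' (built-in: %s)",
        dialect, paste(names(.EMAPPER_DIALECTS), collapse = ", ")
      ))
    }
    return(.EMAPPER_DIALECTS[[dialect]])
  }
  stopifnot(
    is.list(dialect),
    all(c("ncol", "query", "seed_ortholog", "evalue", "gene", "description")
        %in% names(dialect))
  )
  dialect
}

.absent <- function(x) is.na(x) | x == "-" | x == ""

#' Parse an eggNOG-mapper annotation table
#'
#' Reads the tab-delimited `.emapper.annotations` dialect: lines starting with
#' `#` are comments, every data row must have the dialect's column count.
#' Missing fields (`-` or empty) become `NA`. Each record is categorized:
#' `gene_assigned` when a preferred gene name is present, `unassigned` when no
#' ortholog hit passed the mapper's threshold (seed ortholog absent),
#' `function_only` otherwise.
#'
#' @param path Path to the annotation table.
#' @param dialect `"v2"` (default, 21-column emapper 2.x layout), `"v1"`
#'   (13-column 2019 web-service layout), or a list with elements `ncol`,
#'   `query`, `seed_ortholog`, `evalue`, `gene`, `description` giving column
#'   positions.
#' @return A tibble with columns `query_id`, `seed_ortholog`, `evalue`,
#'   `gene_name`, `description`, `category`.
#' @export
parse_emapper <- function(path, dialect = "v2") {
  d <- .resolve_dialect(dialect)
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(data_idx)) {
    return(tibble(
      query_id = character(), seed_ortholog = character(), evalue = numeric(),
      gene_name = character(), description = character(), category = character()
    ))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != d$ncol)
  if (length(bad)) {
    abort(sprintf(
      "line %d: expected %d tab-separated columns, found %d",
      data_idx[bad[1]], d$ncol, nf[bad[1]]
    ))
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  query_id <- col(d$query)
  seed <- col(d$seed_ortholog)
  evalue <- suppressWarnings(as.numeric(col(d$evalue)))
  gene <- col(d$gene)
  desc <- col(d$description)

  seed[.absent(seed)] <- NA_character_
  gene[.absent(gene)] <- NA_character_
  desc[.absent(desc)] <- NA_character_

  inconsistent <- is.na(seed) & !is.na(gene)
  if (any(inconsistent)) {
    abort(sprintf(
      "line %d: gene name present without a seed ortholog hit",
      data_idx[which(inconsistent)[1]]
    ))
  }
  category <- ifelse(
    is.na(seed), "unassigned",
    ifelse(!is.na(gene), "gene_assigned", "function_only")
  )
  tibble(
    query_id = query_id, seed_ortholog = seed, evalue = evalue,
    gene_name = gene, description = desc, category = category
  )
}

#' Categorize annotated queries into gene / function / unassigned counts
#'
#' Partitions the queried ids into the three annotation outcomes:
#' `gene_assigned` (a specific gene name was assigned), `function_only`
#' (ortholog hit with functional description but no gene name) and
#' `unassigned` (no row in the table, or a row without a passing ortholog
#' hit). Counts always sum to `length(queried_ids)`.
#'
#' @param annotations Tibble from [parse_emapper()].
#' @param queried_ids Character vector of all ids that were submitted for
#'   annotation; must be a superset of the table's query ids.
#' @return A tibble with columns `category` and `n`, one row per category.
#' @export
categorize_annotations <- function(annotations, queried_ids) {
  queried_ids <- unique(as.character(queried_ids))
  stray <- setdiff(annotations$query_id, queried_ids)
  if (length(stray)) {
    abort(sprintf(
      "%d annotation query id(s) not in `queried_ids`, e.g. %s",
      length(stray), stray[1]
    ))
  }
  ids_gene <- unique(annotations$query_id[annotations$category == "gene_assigned"])
  ids_fun <- unique(annotations$query_id[annotations$category == "function_only"])
  n_gene <- length(ids_gene)
  n_fun <- length(setdiff(ids_fun, ids_gene))
  tibble(
    category = c("gene_assigned", "function_only", "unassigned"),
    n = c(n_gene, n_fun, length(queried_ids) - n_gene - n_fun)
  )
}

#' Merge eggNOG annotations into an annotated protein FASTA
#'
#' Rewrites headers to the three-field form
#' `{query_id}|{gene}|{description}`, where `gene` is the assigned gene name
#' or the literal placeholder `"gene not found"` when annotation was by
#' function only (or absent). Sequences and record order are untouched;
#' records with no annotation row pass through with the placeholder gene and
#' an empty description.
#'
#' @param fasta Tibble of protein records (every annotation `query_id` must
#'   occur among its ids).
#' @param annotations Tibble from [parse_emapper()].
#' @param keep_best If a query id has several annotation rows, keep the
#'   smallest-e-value row instead of raising an error.
#' @return A tibble of class `annotated_fasta` with columns `query_id`,
#'   `gene`, `description`, `category`, `sequence`, `header`; the per-category
#'   counts are attached as attribute `category_counts` (see [glance()]).
#' @export
merge_annotations <- function(fasta, annotations, keep_best = FALSE) {
  stopifnot(is.data.frame(fasta), is.data.frame(annotations))
  missing <- setdiff(annotations$query_id, fasta$id)
  if (length(missing)) {
    abort(sprintf(
      "%d annotation query id(s) missing from the FASTA, e.g. %s",
      length(missing), missing[1]
    ))
  }
  dup <- unique(annotations$query_id[duplicated(annotations$query_id)])
  if (length(dup)) {
    if (!keep_best) {
      abort(sprintf(
        "duplicate annotations for %d id(s), e.g. '%s'; set keep_best = TRUE to keep the smallest e-value",
        length(dup), dup[1]
      ))
    }
    annotations <- annotations |>
      arrange(.data$query_id, .data$evalue) |>
      filter(!duplicated(.data$query_id))
  }
  ann <- select(
    annotations, "query_id", "gene_name", "description", "category"
  )
  out <- fasta |>
    select(query_id = "id", "sequence") |>
    left_join(ann, by = "query_id") |>
    mutate(
      category = ifelse(is.na(.data$category), "unassigned", .data$category),
      gene = ifelse(is.na(.data$gene_name), "gene not found", .data$gene_name),
      description = ifelse(is.na(.data$description), "", .data$description),
      header = paste(.data$query_id, .data$gene, .data$description, sep = "|")
    ) |>
    select("query_id", "gene", "description", "category", "sequence", "header")
  counts <- tibble(
    category = c("gene_assigned", "function_only", "unassigned"),
    n = vapply(
      c("gene_assigned", "function_only", "unassigned"),
      function(cc) sum(out$category == cc), integer(1), USE.NAMES = FALSE
    )
  )
  structure(
    out,
    class = c("annotated_fasta", class(out)),
    category_counts = counts
  )
}

#' @exportS3Method generics::glance
glance.annotated_fasta <- function(x, ...) {
  counts <- attr(x, "category_counts")
  tidyr::pivot_wider(counts, names_from = "category", values_from = "n") |>
    mutate(n_records = nrow(x))
}

#' Write an annotated FASTA produced by [merge_annotations()]
#'
#' Headers are the full `query|gene|description` strings; sequence lines wrap
#' at 60 columns.
#'
#' @param x An `annotated_fasta` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("header", "sequence") %in% names(x)))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$header
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an annotated FASTA back into its structured fields
#'
#' Reconstructs `query_id`, `gene` and `description` by splitting the full
#' header on the first two `|` delimiters.
#'
#' @param path Path to a FASTA written by [write_annotated_fasta()].
#' @return A tibble with columns `query_id`, `gene`, `description`,
#'   `sequence`.
#' @export
read_annotated_fasta <- function(path) {
  rec <- read_fasta(path)
  full <- ifelse(
    nzchar(rec$description), paste(rec$id, rec$description), rec$id
  )
  parts <- stringr::str_split_fixed(full, stringr::fixed("|"), 3)
  tibble(
    query_id = parts[, 1],
    gene = parts[, 2],
    description = parts[, 3],
    sequence = rec$sequence
  )
}
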