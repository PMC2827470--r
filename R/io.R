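#' Signature tables
#'
#' A signature table is the unit all downstream comparisons operate on: one
#' row per probe with its gene id, signed log2 fold change and P-value.
#' `background_size` (the number of probes surveyed, carried in the file as a
#' `#background=` comment line) defines the universe for enrichment nulls;
#' `alpha` is set once a table has been significance-filtered.
#'
#' @param probe_id,gene_id Character vectors.
#' @param log2fc Numeric signed log2 fold changes (finite).
#' @param p_value Numeric P-values in (0, 1].
#' @param background_size Optional count of probes surveyed.
#' @param alpha Optional significance level the table was filtered at.
#' @param extra Optional data.frame of additional (opaque) annotation columns.
#' @return A data.frame of class `signature_table` with columns `probe_id`,
#'   `gene_id`, `log2fc`, `p_value`, `direction`, plus any extra columns.
#' @export
signature_table <- function(probe_id, gene_id, log2fc, p_value,
                            background_size = NA_integer_, alpha = NA_real_,
                            extra = NULL) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id in signature table: ",
         probe_id[duplicated(probe_id)][1])
  if (any(!is.finite(log2fc)))
    stop("log2fc must be finite for every row")
  if (any(!is.finite(p_value) | p_value <= 0 | p_value > 1))
    stop("p_value must lie in (0, 1] for every row")
  tab <- data.frame(probe_id = probe_id, gene_id = gene_id,
                    log2fc = as.numeric(log2fc),
                    p_value = as.numeric(p_value),
                    direction = ifelse(log2fc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  if (!is.null(extra) && ncol(extra)) tab <- cbind(tab, extra)
  attr(tab, "background_size") <- as.integer(background_size)
  attr(tab, "alpha") <- as.numeric(alpha)
  class(tab) <- c("signature_table", "data.frame")
  tab
}

#' @export
print.signature_table <- function(x, ...) {
  bg <- attr(x, "background_size")
  al <- attr(x, "alpha")
  cat(sprintf("signature_table: %d probes, %d genes%s%s\n",
              nrow(x), length(unique(x$gene_id)),
              if (!is.na(bg)) sprintf(", background %d", bg) else "",
              if (!is.na(al)) sprintf(", alpha %g", al) else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

.sig_required <- c("probe_id", "gene_id", "log2fc", "p_value")

#' Read a signature CSV
#'
#' Canonical columns are `probe_id`, `gene_id`, `log2fc`, `p_value`;
#' supplementary-style files with different headers are read by supplying an
#' alias map. Leading `#` comment lines are scanned for `#background=N`.
#' Unknown extra columns are preserved as opaque annotation text. Malformed
#' numeric fields are rejected with the offending line number.
#'
#' @param path Path to a CSV file.
#' @param aliases Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(probe_id = "Probe ID")`.
#' @return A [signature_table()].
#' @export
read_signature_csv <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^#", lines)
  n_lead <- if (any(!is_comment)) which(!is_comment)[1] - 1L else length(lines)
  background_size <- NA_integer_
  bg_line <- grep("^#background=", lines[seq_len(n_lead)], value = TRUE)
  if (length(bg_line))
    background_size <- as.integer(sub("^#background=", "", bg_line[1]))
  body <- lines[!is_comment]
  if (!length(body)) stop("format error: no header line in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  cols <- names(df)
  for (canon in .sig_required) {
    actual <- if (!is.null(aliases) && canon %in% names(aliases))
      aliases[[canon]] else canon
    if (!actual %in% cols)
      stop("format error: missing required column '", actual, "' in ", path)
    names(df)[cols == actual] <- canon
    cols <- names(df)
  }
  # data row i sits on physical line: leading comments + header + i
  line_no <- n_lead + 1L + seq_len(nrow(df))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]])
    bad <- bad | is.na(df[[col]])
    if (any(bad))
      stop("parse error: non-numeric ", col, " at line ", line_no[bad][1],
           " of ", path)
    v
  }
  extra_cols <- setdiff(names(df), c(.sig_required, "direction"))
  extra <- if (length(extra_cols)) df[, extra_cols, drop = FALSE] else NULL
  signature_table(df$probe_id, df$gene_id, num("log2fc"), num("p_value"),
                  background_size = background_size, extra = extra)
}

#' Write a signature CSV
#'
#' Inverse of [read_signature_csv()]: canonical header, a `#background=N`
#' comment line when the background size is known, extra columns preserved.
#'
#' @param table A [signature_table()].
#' @param path Output path.
#' @export
write_signature_csv <- function(table, path) {
  stopifnot(inherits(table, "signature_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  bg <- attr(table, "background_size")
  if (!is.na(bg)) writeLines(sprintf("#background=%d", bg), con)
  out <- as.data.frame(table)
  out$direction <- NULL
  out$log2fc <- sprintf("%.15g", out$log2fc)
  out$p_value <- sprintf("%.15g", out$p_value)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one pathway per line: name, description, then member gene
#' ids. Duplicate members within a set are deduplicated; empty sets and lines
#' with fewer than 3 fields are rejected with their line number.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_annotation()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("format error: fewer than 3 tab-separated fields at line ", i,
           " of ", path)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("format error: empty gene set '", f[1], "' at line ", i, " of ",
           path)
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  pathway_annotation(sets, descriptions = descs)
}

#' Write a GMT gene-set file
#' @param ann A [pathway_annotation()].
#' @param path Output path.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "pathway_annotation"))
  lines <- vapply(names(ann$sets), function(id) {
    paste(c(id, ann$descriptions[[id]], ann$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Pajek network container
#'
#' Plain-text graph representation for network visualization: an ordered
#' vertex list (1-based contiguous ids, quoted labels, optional color token)
#' and an undirected weighted edge list.
#'
#' @param vertices data.frame with columns `id` (1-based contiguous
#'   integers), `label` (character) and optionally `color`.
#' @param edges data.frame with columns `from`, `to` (vertex ids) and
#'   `weight` (non-negative).
#' @return An object of class `pajek_network`.
#' @export
pajek_network <- function(vertices = data.frame(id = integer(),
                                                label = character(),
                                                color = character()),
                          edges = data.frame(from = integer(),
                                             to = integer(),
                                             weight = numeric())) {
  vertices <- as.data.frame(vertices)
  edges <- as.data.frame(edges)
  if (!"color" %in% names(vertices)) vertices$color <- NA_character_
  if (nrow(vertices) &&
      !identical(as.integer(vertices$id), seq_len(nrow(vertices))))
    stop("vertex ids must be contiguous from 1")
  if (nrow(edges)) {
    ok <- edges$from %in% vertices$id & edges$to %in% vertices$id
    if (!all(ok))
      stop("validation error: edge endpoint(s) reference missing vertices")
    if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  }
  structure(list(vertices = vertices[, c("id", "label", "color")],
                 edges = edges[, c("from", "to", "weight"), drop = FALSE]),
            class = "pajek_network")
}

#' @export
print.pajek_network <- function(x, ...) {
  cat(sprintf("pajek_network: %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Write a network in Pajek .net format
#'
#' Emits the standard dialect: a `*Vertices N` section with quoted labels
#' (and an `ic <color>` token when a vertex has a color), then an `*Edges`
#' section with `from to weight` triples. An empty network is exactly the
#' two section headers.
#'
#' @param net A [pajek_network()].
#' @param path Output path.
#' @export
write_pajek <- function(net, path) {
  stopifnot(inherits(net, "pajek_network"))
  v <- net$vertices
  vlines <- if (nrow(v)) {
    paste0(v$id, " \"", v$label, "\"",
           ifelse(is.na(v$color) | !nzchar(v$color), "",
                  paste0(" ic ", v$color)))
  } else character()
  e <- net$edges
  elines <- if (nrow(e)) sprintf("%d %d %.15g", e$from, e$to, e$weight)
            else character()
  writeLines(c(sprintf("*Vertices %d", nrow(v)), vlines, "*Edges", elines),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Inverse of [write_pajek()] on the dialect it emits.
#'
#' @param path Path to a .net file.
#' @return A [pajek_network()].
#' @export
read_pajek <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  ehead <- grep("^\\*Edges", lines, ignore.case = TRUE)
  if (!length(vhead) || !length(ehead))
    stop("format error: missing *Vertices or *Edges section in ", path)
  n_v <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead[1]],
                        ignore.case = TRUE))
  vlines <- lines[setdiff(seq(vhead[1] + 1L, length.out = ehead[1] - vhead[1] - 1L),
                          integer(0))]
  vlines <- vlines[nzchar(trimws(vlines))]
  if (length(vlines) != n_v)
    stop("format error: *Vertices announces ", n_v, " vertices but ",
         length(vlines), " follow in ", path)
  parse_v <- function(s) {
    m <- regmatches(s, regexec('^\\s*(\\d+)\\s+"([^"]*)"(?:\\s+ic\\s+(\\S+))?',
                               s))[[1]]
    if (!length(m)) stop("format error: unparseable vertex line: ", s)
    list(id = as.integer(m[2]), label = m[3],
         color = if (nzchar(m[4])) m[4] else NA_character_)
  }
  vparsed <- lapply(vlines, parse_v)
  vertices <- data.frame(id = vapply(vparsed, `[[`, integer(1), "id"),
                         label = vapply(vparsed, `[[`, character(1), "label"),
                         color = vapply(vparsed, `[[`, character(1), "color"),
                         stringsAsFactors = FALSE)
  elines <- if (ehead[1] < length(lines))
    lines[(ehead[1] + 1L):length(lines)] else character()
  elines <- elines[nzchar(trimws(elines))]
  edges <- if (length(elines)) {
    parts <- strsplit(trimws(elines), "\\s+")
    data.frame(from = as.integer(vapply(parts, `[`, character(1), 1)),
               to = as.integer(vapply(parts, `[`, character(1), 2)),
               weight = as.numeric(vapply(parts, function(p)
                 if (length(p) >= 3) p[3] else "1", character(1))))
  } else data.frame(from = integer(), to = integer(), weight = numeric())
  pajek_network(vertices, edges)
}

#' Read / write a probe-to-gene map (TSV)
#'
#' Two tab-separated columns, `probe_id` and `gene_id`, with a header line.
#' Many probes may map to one gene; empty gene ids are rejected.
#'
#' @param path Path to a TSV file.
#' @param platform Optional platform label attached as an attribute.
#' @return A data.frame of class `probe_map` with columns `probe_id`,
#'   `gene_id`.
#' @export
read_probe_map <- function(path, platform = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stop("format error: probe map must have columns probe_id, gene_id")
  probe_map(df$probe_id, df$gene_id, platform = platform)
}

#' @rdname read_probe_map
#' @param map A `probe_map`.
#' @export
write_probe_map <- function(map, path) {
  stopifnot(inherits(map, "probe_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a probe-to-gene map
#' @param probe_id,gene_id Character vectors of equal length.
#' @param platform Optional platform label.
#' @return A data.frame of class `probe_map`.
#' @export
probe_map <- function(probe_id, gene_id, platform = NA_character_) {
  probe_id <- as.character(probe_id); gene_id <- as.character(gene_id)
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id in probe map: ",
         probe_id[duplicated(probe_id)][1])
  bad <- !nzchar(gene_id) | is.na(gene_id)
  if (any(bad)) stop("empty gene_id for probe ", probe_id[bad][1])
  structure(data.frame(probe_id = probe_id, gene_id = gene_id,
                       stringsAsFactors = FALSE),
            platform = platform, class = c("probe_map", "data.frame"))
}

#' Write an expression study to plain-text files
#'
#' Writes the intensity matrix as CSV (probe ids in the first column, one
#' column per sample), the sample-to-group assignment as TSV, the probe map
#' as TSV, and — for synthetic studies — the planted truth as a sidecar CSV
#' with columns `probe_id`, `gene_id`, `true_log2fc`, `in_signature`.
#'
#' @param study An `expression_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the files written.
#' @export
write_study <- function(study, dir, prefix = "study") {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    intensities = file.path(dir, paste0(prefix, "_intensities.csv")),
    groups = file.path(dir, paste0(prefix, "_groups.tsv")),
    probe_map = file.path(dir, paste0(prefix, "_probe_map.tsv"))
  )
  m <- data.frame(probe_id = rownames(study$intensities),
                  study$intensities, check.names = FALSE)
  utils::write.csv(m, paths[["intensities"]], row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(sample = colnames(study$intensities),
                                group = study$group_labels),
                     paths[["groups"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_probe_map(study$probe_gene_map, paths[["probe_map"]])
  if (!is.null(study$truth)) {
    paths[["truth"]] <- file.path(dir, paste0(prefix, "_truth.csv"))
    tr <- study$truth
    map <- study$probe_gene_map
    sidecar <- data.frame(
      probe_id = map$probe_id,
      gene_id = map$gene_id,
      true_log2fc = ifelse(map$probe_id %in% names(tr$true_log2fc),
                           tr$true_log2fc[map$probe_id], 0),
      in_signature = map$probe_id %in% tr$signature_probes)
    utils::write.csv(sidecar, paths[["truth"]], row.names = FALSE,
                     quote = FALSE)
  }
  invisible(paths)
}

#' Read an expression study from the files written by [write_study()]
#'
#' @param intensities_path,groups_path,map_path Paths to the CSV/TSV files.
#' @return An `expression_study` (without planted truth).
#' @export
read_study <- function(intensities_path, groups_path, map_path) {
  m <- utils::read.csv(intensities_path, check.names = FALSE)
  probes <- m$probe_id
  m$probe_id <- NULL
  mat <- as.matrix(m)
  rownames(mat) <- probes
  groups <- utils::read.delim(groups_path, colClasses = "character")
  labels <- stats::setNames(groups$group, groups$sample)[colnames(mat)]
  expression_study(mat, labels, read_probe_map(map_path))
}
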