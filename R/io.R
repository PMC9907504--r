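# cluster JSON dialect:
# [{cluster_id, genome_id, class, is_reference, compound,
#   genes: [{gene_id, order_index, strand, role_annotation,
#            domains: [...], sequence}]}, ...]

#' Read and write the cluster JSON dialect
#'
#' @param path File path.
#' @return `read_bgc_json()`: clusters tibble with nested `genes`.
#' @export
read_bgc_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bind_rows(lapply(raw, function(cl) {
    genes <- bind_rows(lapply(cl$genes, function(g) {
      tibble(gene_id = g$gene_id, order_index = g$order_index,
             strand = g$strand %||% "+",
             role_annotation = g$role_annotation %||% NA_character_,
             domains = list(unlist(g$domains) %||% character()),
             sequence = g$sequence)
    })) |> arrange(.data$order_index)
    tibble(cluster_id = cl$cluster_id, genome_id = cl$genome_id,
           class = cl$class, is_reference = isTRUE(cl$is_reference),
           compound = cl$compound %||% NA_character_, genes = list(genes))
  }))
}

#' @rdname read_bgc_json
#' @param clusters Clusters tibble with nested `genes`.
#' @export
write_bgc_json <- function(clusters, path) {
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    genes <- cl$genes[[1]]
    list(cluster_id = cl$cluster_id, genome_id = cl$genome_id,
         class = cl$class, is_reference = cl$is_reference,
         compound = if (is.na(cl$compound)) NULL else cl$compound,
         genes = lapply(seq_len(nrow(genes)), function(j) {
           list(gene_id = genes$gene_id[j],
                order_index = genes$order_index[j],
                strand = genes$strand[j],
                role_annotation = genes$role_annotation[j],
                domains = as.list(genes$domains[[j]]),
                sequence = genes$sequence[j])
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read/write presence-absence matrices as TSV
#'
#' Rows are genomes, columns families, cells 0/1; the first column holds
#' the genome id.
#'
#' @param pa Wide tibble or binary matrix.
#' @param path File path.
#' @export
write_pa_tsv <- function(pa, path) {
  if (is.matrix(pa)) {
    if (is.null(colnames(pa))) {
      colnames(pa) <- sprintf("fam%03d", seq_len(ncol(pa)))
    }
    pa <- dplyr::bind_cols(tibble(genome_id = rownames(pa)), as_tibble(pa))
  }
  readr::write_tsv(pa, path)
  invisible(path)
}

#' @rdname write_pa_tsv
#' @export
read_pa_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
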