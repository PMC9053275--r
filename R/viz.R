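#' Four-region one-hot representation of a label vector
#'
#' Collapses a 25-sign label vector to four bits: presence of at least one
#' abnormal sign in the thoracic wall (`y_th`), mediastinum (`y_me`), lung
#' parenchyma (`y_lp`) and pleura (`y_pl`).
#'
#' @param vector Named 0/1 vector over the graph's leaf labels (or a
#'   one-row label tibble; a `subject_id` column is ignored).
#' @param graph A [knowledge_graph()].
#' @return Named integer vector `c(y_th, y_me, y_lp, y_pl)`.
#' @export
region_onehot <- function(vector, graph) {
  if (is.data.frame(vector)) {
    vector <- unlist(vector[1, setdiff(names(vector), "subject_id")])
  }
  ids <- label_ids(graph)
  unknown <- setdiff(names(vector), ids)
  if (length(unknown) > 0L) {
    abort(paste0("labels not in ontology: ", paste(unknown, collapse = ", ")))
  }
  if (!setequal(names(vector), ids)) {
    abort("label vector must cover every leaf label")
  }
  regions <- region_of_label(graph, names(vector))
  on <- function(r) as.integer(any(vector[regions == r] == 1))
  c(
    y_th = on("thoracic_wall"), y_me = on("mediastinum"),
    y_lp = on("lung_parenchyma"), y_pl = on("pleura")
  )
}

#' 4-bit anatomical color index
#'
#' `CI = y_th * 8 + y_me * 4 + y_lp * 2 + y_pl * 1`: a bijective binary
#' encoding of which anatomical regions carry at least one abnormal sign,
#' used to color subjects in embedding plots. Normal subjects code as 0; a
#' single abnormal sign in the thoracic wall, mediastinum, lung parenchyma
#' or pleura codes as 8, 4, 2 or 1; multiple regions code as the sum.
#'
#' @param onehot Named vector from [region_onehot()] (names `y_th`, `y_me`,
#'   `y_lp`, `y_pl`).
#' @return Integer in `[0, 15]`.
#' @examples
#' color_index(c(y_th = 0, y_me = 1, y_lp = 1, y_pl = 0)) # 6
#' @export
color_index <- function(onehot) {
  need <- c("y_th", "y_me", "y_lp", "y_pl")
  if (!all(need %in% names(onehot))) {
    abort("onehot must have components y_th, y_me, y_lp, y_pl")
  }
  v <- as.integer(onehot[need])
  if (!all(v %in% c(0L, 1L))) abort("onehot components must be 0/1")
  v[1] * 8L + v[2] * 4L + v[3] * 2L + v[4] * 1L
}

#' @rdname color_index
#' @param ci Integer color index in `[0, 15]`.
#' @return `decode_color_index()`: the named one-hot vector.
#' @export
decode_color_index <- function(ci) {
  ci <- as.integer(ci)
  if (ci < 0L || ci > 15L) abort("color index must lie in [0, 15]")
  c(
    y_th = ci %/% 8L %% 2L, y_me = ci %/% 4L %% 2L,
    y_lp = ci %/% 2L %% 2L, y_pl = ci %% 2L
  )
}

#' Embedding export table with per-subject color indices
#'
#' Computes the color index for every subject of a label matrix and
#' attaches optional 2-D embedding coordinates (e.g. from an external
#' t-SNE/UMAP run) unchanged. Dimensionality reduction itself is out of
#' scope; this table is its input/output contract.
#'
#' @param matrix Label matrix from [build_label_matrix()].
#' @param graph A [knowledge_graph()].
#' @param coordinates Optional data frame/matrix of two columns (`x`, `y`)
#'   aligned with the subjects (or with a `subject_id` column to align by).
#' @return Tibble of class `embedding_table`: `subject_id`, `color_index`,
#'   `x`, `y`.
#' @export
export_embedding_table <- function(matrix, graph, coordinates = NULL) {
  vals <- matrix_values(matrix)
  ids <- label_ids(graph)
  if (!setequal(colnames(vals), ids)) abort("matrix labels must match the ontology")
  regions <- region_of_label(graph, colnames(vals))
  bits <- cbind(
    (vals[, regions == "thoracic_wall", drop = FALSE] %*% rep(1, sum(regions == "thoracic_wall"))) > 0,
    (vals[, regions == "mediastinum", drop = FALSE] %*% rep(1, sum(regions == "mediastinum"))) > 0,
    (vals[, regions == "lung_parenchyma", drop = FALSE] %*% rep(1, sum(regions == "lung_parenchyma"))) > 0,
    (vals[, regions == "pleura", drop = FALSE] %*% rep(1, sum(regions == "pleura"))) > 0
  )
  ci <- as.integer(bits %*% c(8L, 4L, 2L, 1L))
  out <- tibble(
    subject_id = as.character(matrix$subject_id),
    color_index = ci, x = NA_real_, y = NA_real_
  )
  if (!is.null(coordinates)) {
    coordinates <- as.data.frame(coordinates)
    if ("subject_id" %in% names(coordinates)) {
      idx <- match(out$subject_id, as.character(coordinates$subject_id))
      if (anyNA(idx)) abort("coordinates do not cover every subject")
      coordinates <- coordinates[idx, setdiff(names(coordinates), "subject_id")]
    } else if (nrow(coordinates) != nrow(out)) {
      abort("coordinates must align with the subjects")
    }
    if (ncol(coordinates) != 2L) abort("coordinates must have two columns")
    out$x <- as.numeric(coordinates[[1]])
    out$y <- as.numeric(coordinates[[2]])
  }
  class(out) <- c("embedding_table", class(out))
  out
}
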