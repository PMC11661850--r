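# Plain-text persistence: tensor stores with signature metadata, run
# configurations, JSON-lines logs, model checkpoints, and an optional
# PDB-backed point-cloud reader.

#' Write a batch of steerable tensors to a JSON store
#'
#' The store records the signature, the flat coefficient vectors (in
#' [st_flatten()] order), and optional labels and metadata, at full double
#' precision.
#'
#' @param tensors List of `steerable_tensor`s with equal signatures.
#' @param path Output path.
#' @param labels Optional per-tensor labels.
#' @param metadata Optional named list stored verbatim.
#' @export
write_tensor_store <- function(tensors, path, labels = NULL, metadata = NULL) {
  if (length(tensors) == 0) stop("empty tensor list")
  sig <- st_signature(tensors[[1]])
  for (t in tensors) if (!sig_equal(st_signature(t), sig))
    stop("all tensors must share one signature")
  payload <- list(degrees = sig$degrees, channels = sig$channels,
                  n = length(tensors),
                  values = lapply(tensors, st_flatten))
  if (!is.null(labels)) payload$labels <- as.character(labels)
  if (!is.null(metadata)) payload$metadata <- metadata
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tensor store written by [write_tensor_store()]
#'
#' @param path Store path.
#' @return List with `tensors`, `labels` (or NULL), `metadata` (or NULL).
#' @export
read_tensor_store <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- tensor_signature(payload$degrees, payload$channels)
  vals <- payload$values
  if (is.matrix(vals)) vals <- asplit(vals, 1)
  tensors <- lapply(vals, st_unflatten, sig = sig)
  list(tensors = tensors, labels = payload$labels, metadata = payload$metadata)
}

#' Save a model checkpoint as JSON
#'
#' Self-describing: stores the configuration, all parameters, and the
#' normalization running statistics, so [load_hvae_model()] reproduces the
#' model bit-exactly.
#'
#' @param model An [hvae_model()].
#' @param path Output path.
#' @export
save_hvae_model <- function(model, path) {
  cfg <- model$config
  ser <- function(p) {
    if (is.list(p)) return(lapply(p, ser))
    list(dim = dim(p) %||% length(p), values = as.vector(p))
  }
  payload <- list(
    config = list(degrees = cfg$input_sig$degrees,
                  channels = cfg$input_sig$channels,
                  latent_dim = cfg$latent_dim, hidden = cfg$hidden,
                  variational = cfg$variational,
                  condition_size = cfg$condition_size,
                  encoder_caps = cfg$encoder_caps,
                  decoder_caps = cfg$decoder_caps,
                  block_order = cfg$block_order, seed = cfg$seed),
    params = ser(model$params),
    states = ser(model$states))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_hvae_model()]
#'
#' @param path Checkpoint path.
#' @return An [hvae_model()].
#' @export
load_hvae_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cf <- payload$config
  config <- hvae_config(tensor_signature(unlist(cf$degrees),
                                         unlist(cf$channels)),
                        latent_dim = cf$latent_dim, hidden = cf$hidden,
                        variational = cf$variational,
                        condition_size = cf$condition_size,
                        encoder_caps = unlist(cf$encoder_caps),
                        decoder_caps = unlist(cf$decoder_caps),
                        block_order = unlist(cf$block_order), seed = cf$seed)
  model <- hvae_model(config)
  deser <- function(node, skeleton) {
    if (is.list(skeleton)) {
      out <- lapply(seq_along(skeleton), function(i)
        deser(node[[i]], skeleton[[i]]))
      names(out) <- names(skeleton)
      return(out)
    }
    v <- as.numeric(unlist(node$values))
    dims <- as.integer(unlist(node$dim))
    if (length(dims) > 1) dim(v) <- dims
    v
  }
  model$params <- deser(payload$params, model$params)
  model$states <- deser(payload$states, model$states)
  model
}

#' Read a plain-text run configuration (key = value lines)
#'
#' Lines starting with `#` and blank lines are ignored; values are parsed
#' as numbers where possible.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Append a record to a JSON-lines log
#'
#' @param record Named list (one log entry).
#' @param path Log file path (created if missing).
#' @export
append_jsonl <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Residue-centered point clouds from a PDB file
#'
#' Optional convenience reader (requires the `bio3d` package): for every
#' residue with a C-alpha atom, collects the heavy atoms within `r_max`
#' angstroms of that C-alpha (the residue's structural neighborhood, or
#' only the residue's own atoms with `mode = "residue"`), centered at the
#' C-alpha, with element labels as channels.
#'
#' @param path PDB file path.
#' @param r_max Neighborhood radius in angstroms.
#' @param mode `"neighborhood"` (all atoms within `r_max`) or `"residue"`
#'   (own atoms only).
#' @param channels Element labels kept (others are dropped).
#' @return List of `labeled_point_cloud`s, named by chain and residue.
#' @export
pdb_point_clouds <- function(path, r_max = 10,
                             mode = c("neighborhood", "residue"),
                             channels = c("C", "N", "O", "S")) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("pdb_point_clouds() requires the bio3d package")
  mode <- match.arg(mode)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$elesy %in% channels, , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ca))) {
    center <- as.numeric(ca[i, c("x", "y", "z")])
    sel <- if (mode == "residue")
      at$resno == ca$resno[i] & at$chain %in% ca$chain[i]
    else rep(TRUE, nrow(at))
    pts <- as.matrix(at[sel, c("x", "y", "z")])
    pts <- sweep(pts, 2, center)
    keep <- sqrt(rowSums(pts^2)) <= r_max
    if (!any(keep)) next
    out[[paste0(ca$chain[i], ca$resno[i])]] <-
      labeled_point_cloud(pts[keep, , drop = FALSE], at$elesy[sel][keep])
  }
  out
}
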