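## Plain-text persistence of assembled networks: a directory with the frame
## tables, the cell-type table, the neuron table, flattened rigid transforms,
## and the morphology library as SWC files.

#' Write a network model to a directory
#'
#' @param network a [NetworkModel-class]
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeNetwork <- function(network, dir) {
  dir.create(file.path(dir, "swc"), showWarnings = FALSE, recursive = TRUE)
  g <- network@frame@grid
  writeLines(sprintf(
    '{"origin": [%s], "spacing": %g, "dims": [%s], "k": %d}',
    paste(g@origin, collapse = ", "), g@spacing,
    paste(g@dims, collapse = ", "), network@frame@k),
    file.path(dir, "grid.json"))
  write.csv(network@frame@columns, file.path(dir, "columns.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(network@frame@zones, file.path(dir, "zones.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(network@cellTypes, file.path(dir, "cell_types.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(network@neurons, file.path(dir, "neurons.csv"),
            row.names = FALSE, quote = FALSE)
  tf <- do.call(rbind, lapply(names(network@transforms), function(id) {
    t <- network@transforms[[id]]
    data.frame(id = id, tx = t@translation[1L], ty = t@translation[2L],
               tz = t@translation[3L],
               as.data.frame(matrix(t@rotation, 1L,
                                    dimnames = list(NULL, paste0("r", 1:9)))),
               stringsAsFactors = FALSE)
  }))
  write.csv(tf, file.path(dir, "transforms.csv"), row.names = FALSE,
            quote = FALSE)
  for (id in names(network@morphologies))
    writeSWC(network@morphologies[[id]],
             file.path(dir, "swc", paste0(id, ".swc")))
  invisible(dir)
}

#' Read a network model from a directory
#'
#' Inverse of [writeNetwork].
#' @param dir directory written by [writeNetwork].
#' @return a [NetworkModel-class]
#' @export
readNetwork <- function(dir) {
  gl <- paste(readLines(file.path(dir, "grid.json")), collapse = "")
  num <- function(key) {
    m <- regmatches(gl, regexec(paste0('"', key, '":\\s*\\[?([0-9eE+., -]+)'),
                                gl))[[1L]][2L]
    v <- suppressWarnings(as.numeric(strsplit(m, ",")[[1L]]))
    v[!is.na(v)]
  }
  grid <- VoxelGrid(num("origin"), num("spacing"), as.integer(num("dims")))
  frame <- ReferenceFrame(grid, readColumnTable(file.path(dir, "columns.csv")),
                          readZoneTable(file.path(dir, "zones.csv")),
                          k = as.integer(num("k")))
  cellTypes <- readCellTypeTable(file.path(dir, "cell_types.csv"))
  neurons <- read.csv(file.path(dir, "neurons.csv"),
                      stringsAsFactors = FALSE)
  neurons$id <- as.character(neurons$id)
  neurons$column <- as.character(neurons$column)
  tf <- read.csv(file.path(dir, "transforms.csv"), stringsAsFactors = FALSE)
  transforms <- list()
  for (r in seq_len(nrow(tf)))
    transforms[[as.character(tf$id[r])]] <- RigidTransform(
      translation = unlist(tf[r, c("tx", "ty", "tz")]),
      rotation = matrix(unlist(tf[r, paste0("r", 1:9)]), 3L, 3L))
  files <- list.files(file.path(dir, "swc"), pattern = "\\.swc$")
  morphs <- list()
  for (f in files)
    morphs[[sub("\\.swc$", "", f)]] <- readSWC(file.path(dir, "swc", f))
  nm <- new("NetworkModel", frame = frame, neurons = neurons,
            morphologies = morphs, transforms = transforms,
            cellTypes = cellTypes, cache = new.env(parent = emptyenv()))
  validObject(nm)
  nm
}
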