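#' The 26-class capillary label schema
#'
#' Integer voxel classes 0--25 used by all final label volumes. Classes cover
#' background, basement membrane (BM), endothelial cell (EC) and pericyte (PC)
#' cytosol and organelles, the lumen, electron-lucent pockets (ELPs) in the BM,
#' EC--EC junctions, and the three kinds of peg-and-socket junction
#' (PC peg in EC socket, EC peg in PC socket, EC peg in EC socket) together
#' with peg-internal organelle classes.
#'
#' @return Named integer vector mapping class name to code, codes `0:25`.
#' @examples
#' labelSchema()[["lumen"]]
#' @export
labelSchema <- function() {
  structure(0:25, names = c(
    "background",                 # 0
    "basement_membrane",          # 1
    "EC_cytosol",                 # 2
    "PC_cytosol",                 # 3
    "lumen",                      # 4
    "EC_nucleus",                 # 5
    "PC_nucleus",                 # 6
    "EC_ER",                      # 7
    "PC_ER",                      # 8
    "EC_golgi",                   # 9
    "PC_golgi",                   # 10
    "EC_mitochondria",            # 11
    "PC_mitochondria",            # 12
    "EC_undetermined1",           # 13
    "PC_undetermined1",           # 14
    "EC_undetermined2",           # 15
    "PC_undetermined2",           # 16
    "BM_ELP",                     # 17
    "ECEC_junction",              # 18
    "EC_peg_cytosol",             # 19
    "PC_peg_cytosol",             # 20
    "EC_peg_ER",                  # 21
    "PC_peg_ER",                  # 22
    "EC_peg_mitochondria",        # 23
    "PC_peg_mitochondria",        # 24
    "ECEC_peg"                    # 25
  ))
}

.schemaGroups <- list(
  EC_CYTO  = c(2L, 19L, 21L, 23L),
  PC_CYTO  = c(3L, 20L, 22L, 24L),
  PEG_PC   = c(20L, 22L, 24L),
  PEG_EC   = c(19L, 21L, 23L),
  PEG_ECEC = 25L,
  BM       = c(1L, 17L),
  INTERFACE_CLASSES = c(1L, 17L, 18L),
  # whole-cell groups: cytosol + organelles (+ that cell's peg classes)
  EC_CELL  = c(2L, 5L, 7L, 9L, 11L, 13L, 15L, 19L, 21L, 23L, 25L),
  PC_CELL  = c(3L, 6L, 8L, 10L, 12L, 14L, 16L, 20L, 22L, 24L),
  # organelles by host cell (non-peg)
  EC_ORG   = c(5L, 7L, 9L, 11L, 13L, 15L),
  PC_ORG   = c(6L, 8L, 10L, 12L, 14L, 16L),
  PC_ER    = c(8L, 22L),
  NUCLEI   = c(5L, 6L)
)

#' Derived class groups of the label schema
#'
#' Named subsets of the 0--25 schema codes used throughout the pipeline, e.g.
#' `"EC_CYTO"` (EC cytosol including EC peg cytosol/organelles), `"PC_CYTO"`,
#' `"PEG_PC"`, `"PEG_EC"`, `"PEG_ECEC"`, `"BM"` (basement membrane + BM ELPs),
#' `"INTERFACE_CLASSES"`, `"EC_CELL"`/`"PC_CELL"` (whole cells including
#' organelles and pegs), and `"PC_ER"`.
#'
#' @param name Group name; call with no arguments to list available groups.
#' @return Integer vector of schema codes.
#' @examples
#' classGroup("PEG_PC")
#' @export
classGroup <- function(name) {
  if (missing(name)) return(names(.schemaGroups))
  if (!name %in% names(.schemaGroups))
    stop("unknown class group '", name, "'; available: ",
         paste(names(.schemaGroups), collapse = ", "))
  .schemaGroups[[name]]
}

#' The 7-class semantic schema
#'
#' Classes of a raw semantic prediction volume prior to post-processing:
#' background/cytosol (0), basement membrane (1), lumen (2), nuclei (3),
#' ER (4), mitochondria (5), undetermined (6).
#'
#' @return Named integer vector, codes `0:6`.
#' @export
semanticSchema <- function() {
  structure(0:6, names = c("background_cytosol", "basement_membrane",
                           "lumen", "nuclei", "ER", "mitochondria",
                           "undetermined"))
}
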