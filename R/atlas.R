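#' Region atlas
#'
#' A region atlas is an ordered table of brain regions, one row per
#' region-hemisphere pair, defining the shared index order for every matrix
#' and vector in the pipeline. Rows carry a short abbreviation, a full
#' anatomical name, the hemisphere, and an `in_network` flag marking regions
#' that take part in network analyses (lesioned and excluded structures are
#' flagged `FALSE` but kept in the table so that seed timecourses can still
#' be addressed).
#'
#' The `region` column is the unique region id, `"<abbrev>_<L|R>"`.
#'
#' @param x A data frame with columns `abbrev`, `name`, `hemisphere`
#'   (`"left"` or `"right"`) and `in_network` (logical).
#' @return A `region_atlas` tibble with an additional `region` id column.
#'   Row order is preserved exactly as given.
#' @examples
#' atlas <- regional_map_atlas()
#' n_regions(atlas)
#' n_regions(atlas, network_only = TRUE)
#' @export
region_atlas <- function(x) {
  x <- as_tibble(x)
  needed <- c("abbrev", "name", "hemisphere", "in_network")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(paste0("region table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$hemisphere %in% c("left", "right"))) {
    bad <- unique(x$hemisphere[!x$hemisphere %in% c("left", "right")])
    abort(paste0("unknown hemisphere label(s): ", paste(bad, collapse = ", "),
                 " (expected \"left\" or \"right\")"))
  }
  x$in_network <- as.logical(x$in_network)
  if (anyNA(x$in_network)) abort("in_network must be logical (TRUE/FALSE)")
  key <- paste(x$abbrev, x$hemisphere)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("duplicate (abbreviation, hemisphere) entries: ",
                 paste(dup, collapse = "; ")))
  }
  x$region <- paste0(x$abbrev, "_", ifelse(x$hemisphere == "left", "L", "R"))
  x <- x[, c("region", "abbrev", "name", "hemisphere", "in_network")]
  class(x) <- c("region_atlas", class(tibble()))
  x
}

#' @rdname region_atlas
#' @param atlas A `region_atlas`.
#' @param network_only Count only `in_network` regions?
#' @export
n_regions <- function(atlas, network_only = FALSE) {
  if (network_only) sum(atlas$in_network) else nrow(atlas)
}

#' @rdname region_atlas
#' @export
network_regions <- function(atlas) {
  atlas$region[atlas$in_network]
}

# Table of the 41 Regional Map areas (macroscopic macaque parcellation).
regional_map_areas <- function() {
  tibble::tribble(
    ~abbrev,   ~name,
    "A1",      "Primary auditory cortex",
    "A2",      "Secondary auditory cortex",
    "Amyg",    "Amygdala",
    "CCa",     "Anterior cingulate cortex",
    "CCp",     "Posterior cingulate cortex",
    "CCr",     "Retrosplenial cortex",
    "CCs",     "Subgenual cingulate cortex",
    "FEF",     "Frontal eye field",
    "G",       "Gustatory area",
    "HC",      "Hippocampus",
    "Ia",      "Anterior insula",
    "Ip",      "Posterior insula",
    "M1",      "Primary motor cortex",
    "PCi",     "Inferior parietal cortex",
    "PCip",    "Cortex of the intraparietal sulcus",
    "PCm",     "Medial parietal cortex",
    "PCs",     "Superior parietal cortex",
    "PFCcl",   "Centrolateral prefrontal cortex",
    "PFCdl",   "Dorsolateral prefrontal cortex",
    "PFCdm",   "Dorsomedial prefrontal cortex",
    "PFCm",    "Medial prefrontal cortex",
    "PFCoi",   "Intermediate orbital prefrontal cortex",
    "PFCol",   "Orbitolateral prefrontal cortex",
    "PFCom",   "Orbitomedial prefrontal cortex",
    "PFCpol",  "Polar prefrontal cortex",
    "PFCvl",   "Ventrolateral prefrontal cortex",
    "PHC",     "Parahippocampal cortex",
    "PMCdl",   "Dorsolateral premotor cortex",
    "PMCm",    "Medial (supplementary) premotor cortex",
    "PMCvl",   "Ventrolateral premotor cortex",
    "S1",      "Primary somatosensory cortex",
    "S2",      "Secondary somatosensory cortex",
    "TCc",     "Central temporal cortex",
    "TCi",     "Inferior temporal cortex",
    "TCpol",   "Polar temporal cortex",
    "TCs",     "Superior temporal cortex",
    "TCv",     "Ventral temporal cortex",
    "V1",      "Primary visual cortex",
    "V2",      "Secondary visual cortex",
    "VACd",    "Dorsal anterior visual cortex",
    "VACv",    "Ventral anterior visual cortex"
  )
}

#' Bundled Regional Map atlas
#'
#' The default 82-region atlas: the 41 Regional Map areas duplicated over
#' both hemispheres. The hippocampus and amygdala are flagged
#' `in_network = FALSE` bilaterally (the lesioned structure and its excluded
#' neighbour), leaving 78 network regions. Regions are ordered alphabetically
#' by abbreviation within hemisphere, left hemisphere first; this ordering is
#' a convention of this package, chosen for reproducibility, not an
#' anatomical claim.
#'
#' @return A `region_atlas` tibble with 82 rows.
#' @examples
#' atlas <- regional_map_atlas()
#' subset(atlas, !in_network)
#' @export
regional_map_atlas <- function() {
  areas <- regional_map_areas()
  areas <- areas[order(areas$abbrev), ]
  one <- function(h) {
    tibble(abbrev = areas$abbrev, name = areas$name, hemisphere = h,
           in_network = !areas$abbrev %in% c("HC", "Amyg"))
  }
  region_atlas(bind_rows(one("left"), one("right")))
}

#' Read or write a region table
#'
#' Region tables are tab-delimited UTF-8 text with a header row and columns
#' `abbrev`, `name`, `hemisphere`, `in_network`. Row order in the file is the
#' atlas order.
#'
#' @param path File path.
#' @return `read_region_table()` returns a `region_atlas`;
#'   `write_region_table()` returns `path` invisibly.
#' @export
read_region_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    abbrev = readr::col_character(),
    name = readr::col_character(),
    hemisphere = readr::col_character(),
    in_network = readr::col_logical()
  ))
  region_atlas(x)
}

#' @rdname read_region_table
#' @param atlas A `region_atlas`.
#' @export
write_region_table <- function(atlas, path) {
  readr::write_tsv(atlas[, c("abbrev", "name", "hemisphere", "in_network")],
                   path)
  invisible(path)
}
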