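#' Parcel atlas: the node universe of the connectome
#'
#' A parcel atlas is a data frame with one row per anatomical parcel and
#' columns `id`, `abbreviation`, `name`, `hemisphere` (`"l"`, `"r"` or
#' `"midline"`), `lobe`, `x`, `y`, `z` (MNI millimetres) and `homolog_id`
#' (the id of the contralateral homolog, or `NA` for midline parcels).
#'
#' @param df data frame with the columns above.
#' @return An object of class `parcel_atlas` (a validated data frame).
#' @export
parcel_atlas <- function(df) {
  required <- c("id", "abbreviation", "name", "hemisphere", "lobe",
                "x", "y", "z", "homolog_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("atlas is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, required]
  df$id <- as.integer(df$id)
  df$homolog_id <- as.integer(df$homolog_id)
  if (anyDuplicated(df$id))
    stop("atlas parcel ids must be unique")
  if (anyDuplicated(df[, c("hemisphere", "abbreviation")]))
    stop("atlas abbreviations must be unique within hemisphere")
  if (!all(df$hemisphere %in% c("l", "r", "midline")))
    stop("hemisphere must be one of 'l', 'r', 'midline'")
  ## homolog relation must be symmetric where present
  has_h <- !is.na(df$homolog_id)
  if (any(has_h)) {
    idx <- match(df$homolog_id[has_h], df$id)
    if (anyNA(idx))
      stop("homolog_id refers to unknown parcel ids")
    back <- df$homolog_id[idx]
    if (!all(back == df$id[has_h]))
      stop("homolog pairing is not symmetric")
  }
  rownames(df) <- NULL
  class(df) <- c("parcel_atlas", "data.frame")
  df
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("<parcel_atlas> ", nrow(x), " parcels (",
      sum(x$hemisphere == "l"), " left, ",
      sum(x$hemisphere == "r"), " right, ",
      sum(x$hemisphere == "midline"), " midline), ",
      length(unique(x$lobe)), " lobes\n", sep = "")
  invisible(x)
}

## Cerebral parcel vocabulary: 45 regions per hemisphere, AAL-style
## abbreviations. Lobe labels follow the customary anatomical grouping;
## they drive edge classification and display colouring only.
.cerebral_regions <- function() {
  reg <- function(ab, nm, lobe) data.frame(abbreviation = ab, name = nm,
                                           lobe = lobe,
                                           stringsAsFactors = FALSE)
  rbind(
    reg("F1",   "superior frontal gyrus",                   "frontal"),
    reg("F1O",  "superior frontal gyrus, orbital",          "frontal"),
    reg("F1M",  "superior medial frontal gyrus",            "frontal"),
    reg("F1MO", "superior frontal gyrus, medial orbital",   "frontal"),
    reg("F2",   "middle frontal gyrus",                     "frontal"),
    reg("F2O",  "middle frontal gyrus, orbital",            "frontal"),
    reg("F3OP", "inferior frontal gyrus, pars opercularis", "frontal"),
    reg("F3T",  "inferior frontal gyrus, pars triangularis","frontal"),
    reg("F3O",  "inferior frontal gyrus, pars orbitalis",   "frontal"),
    reg("SMA",  "supplementary motor area",                 "frontal"),
    reg("GR",   "gyrus rectus",                             "frontal"),
    reg("OC",   "olfactory cortex",                         "frontal"),
    reg("PRE",  "precentral gyrus",                         "central"),
    reg("POST", "postcentral gyrus",                        "central"),
    reg("RO",   "rolandic operculum",                       "central"),
    reg("PCL",  "paracentral lobule",                       "central"),
    reg("ACIN", "anterior cingulate gyrus",                 "limbic"),
    reg("MCIN", "middle cingulate gyrus",                   "limbic"),
    reg("PCIN", "posterior cingulate gyrus",                "limbic"),
    reg("HIP",  "hippocampus",                              "limbic"),
    reg("PHIP", "parahippocampal gyrus",                    "limbic"),
    reg("AMYG", "amygdala",                                 "limbic"),
    reg("V1",   "calcarine cortex",                         "occipital"),
    reg("Q",    "cuneus",                                   "occipital"),
    reg("LING", "lingual gyrus",                            "occipital"),
    reg("O1",   "inferior occipital gyrus",                 "occipital"),
    reg("O2",   "middle occipital gyrus",                   "occipital"),
    reg("O3",   "superior occipital gyrus",                 "occipital"),
    reg("FUSI", "fusiform gyrus",                           "occipital"),
    reg("P1",   "superior parietal lobule",                 "parietal"),
    reg("P2",   "inferior parietal lobule",                 "parietal"),
    reg("SMG",  "supramarginal gyrus",                      "parietal"),
    reg("AG",   "angular gyrus",                            "parietal"),
    reg("PQ",   "precuneus",                                "parietal"),
    reg("HES",  "Heschl gyrus",                             "temporal"),
    reg("T1",   "superior temporal gyrus",                  "temporal"),
    reg("T1P",  "superior temporal pole",                   "temporal"),
    reg("T2",   "middle temporal gyrus",                    "temporal"),
    reg("T2P",  "middle temporal pole",                     "temporal"),
    reg("T3",   "inferior temporal gyrus",                  "temporal"),
    reg("IN",   "insula",                                   "insula"),
    reg("CAU",  "caudate nucleus",                          "subcortical"),
    reg("PUT",  "putamen",                                  "subcortical"),
    reg("PAL",  "pallidum",                                 "subcortical"),
    reg("THA",  "thalamus",                                 "subcortical")
  )
}

.cerebellar_regions <- function() {
  reg <- function(ab, nm) data.frame(abbreviation = ab, name = nm,
                                     lobe = "cerebellum",
                                     stringsAsFactors = FALSE)
  rbind(
    reg("CHCL", "cerebellar central lobule"),
    reg("CHCU", "cerebellar culmen"),
    reg("CHS",  "cerebellar lobulus simplex"),
    reg("CHSS", "cerebellar superior semilunar lobule"),
    reg("CHIS", "cerebellar inferior semilunar lobule"),
    reg("CHG",  "cerebellar gracile lobule"),
    reg("CHB",  "cerebellar biventer lobule"),
    reg("CHT",  "cerebellar tonsil"),
    reg("CHF",  "cerebellar flocculus")
  )
}

.vermis_regions <- function() {
  reg <- function(ab, nm) data.frame(abbreviation = ab, name = nm,
                                     lobe = "vermis",
                                     stringsAsFactors = FALSE)
  rbind(
    reg("CVL",  "vermis lingula"),
    reg("CVCL", "vermis central lobule"),
    reg("CVCU", "vermis culmen"),
    reg("CVD",  "vermis declive"),
    reg("CVT",  "vermis tuber"),
    reg("CVP",  "vermis pyramis"),
    reg("CVU",  "vermis uvula"),
    reg("CVN",  "vermis nodulus")
  )
}

## Nominal anterior-posterior (y) and inferior-superior (z) MNI centroids
## per lobe, spread deterministically within each lobe. These are display
## coordinates only; no network quantity depends on them.
.nominal_coords <- function(lobe, k_within, n_within) {
  anchors <- list(
    frontal     = c(y0 =  45, y1 =  10, z =  30),
    central     = c(y0 =  -5, y1 = -30, z =  55),
    limbic      = c(y0 =  35, y1 = -45, z =  10),
    occipital   = c(y0 = -65, y1 = -95, z =   5),
    parietal    = c(y0 = -35, y1 = -70, z =  45),
    temporal    = c(y0 =  10, y1 = -45, z = -15),
    insula      = c(y0 =   5, y1 =   5, z =   5),
    subcortical = c(y0 =  10, y1 = -15, z =   5),
    cerebellum  = c(y0 = -45, y1 = -80, z = -35),
    vermis      = c(y0 = -45, y1 = -75, z = -30)
  )
  a <- anchors[[lobe]]
  t <- if (n_within > 1) (k_within - 1) / (n_within - 1) else 0.5
  c(y = unname(a["y0"] + t * (a["y1"] - a["y0"])), z = unname(a["z"]))
}

#' Packaged default 116-parcel atlas
#'
#' A 116-parcel anatomical atlas in the style of the AAL template: 45 regions
#' per cerebral hemisphere, 9 cerebellar hemispheric regions per side and 8
#' midline vermis regions. Homologous left/right parcels are paired via
#' `homolog_id`; vermis parcels have no homolog. Coordinates are nominal
#' synthetic centroids for display exports only.
#'
#' @return A [parcel_atlas] with 116 rows.
#' @export
default_atlas <- function() {
  paired <- rbind(.cerebral_regions(), .cerebellar_regions())
  rows <- vector("list", 2L * nrow(paired) + 8L)
  id <- 0L
  for (i in seq_len(nrow(paired))) {
    lobe <- paired$lobe[i]
    n_within <- sum(paired$lobe == lobe)
    k_within <- sum(paired$lobe[seq_len(i)] == lobe)
    yz <- .nominal_coords(lobe, k_within, n_within)
    x_abs <- if (lobe == "cerebellum") 25 else 40
    for (side in c("l", "r")) {
      id <- id + 1L
      rows[[id]] <- data.frame(
        id = id, abbreviation = paired$abbreviation[i],
        name = paired$name[i], hemisphere = side, lobe = lobe,
        x = if (side == "l") -x_abs else x_abs,
        y = yz[["y"]], z = yz[["z"]],
        homolog_id = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  vm <- .vermis_regions()
  for (i in seq_len(nrow(vm))) {
    id <- id + 1L
    yz <- .nominal_coords("vermis", i, nrow(vm))
    rows[[id]] <- data.frame(
      id = id, abbreviation = vm$abbreviation[i], name = vm$name[i],
      hemisphere = "midline", lobe = "vermis",
      x = 0, y = yz[["y"]], z = yz[["z"]],
      homolog_id = NA_integer_, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  ## paired parcels were emitted l,r consecutively
  pair_first <- seq(1L, 2L * nrow(paired), by = 2L)
  df$homolog_id[pair_first] <- df$id[pair_first + 1L]
  df$homolog_id[pair_first + 1L] <- df$id[pair_first]
  parcel_atlas(df)
}

#' Read / write a parcel atlas as TSV
#'
#' @param path file path.
#' @return `read_atlas()` returns a [parcel_atlas].
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  parcel_atlas(df)
}

#' @rdname read_atlas
#' @param atlas a [parcel_atlas].
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## internal: unique display label "l PQ" / "r PQ" / "CVD"
.parcel_labels <- function(atlas) {
  ifelse(atlas$hemisphere == "midline", atlas$abbreviation,
         paste(atlas$hemisphere, atlas$abbreviation))
}
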