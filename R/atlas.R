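#' Load a parcellation atlas
#'
#' Reads a delimited table with columns `name`, `hemisphere` and `network`
#' describing an ordered brain parcellation. Cortical regions must carry one
#' of the seven Yeo network labels (`visual`, `somatomotor`,
#' `dorsal_attention`, `ventral_attention`, `limbic`, `frontoparietal`,
#' `default_mode`); subcortical structures carry `subcortical`.
#'
#' @param path Path to a tab- or comma-delimited text file with a header row.
#' @return A `parcellation_atlas`: a data.frame with columns `name`,
#'   `hemisphere`, `network`, in file order.
#' @examples
#' atlas <- default_atlas()
#' nrow(atlas)                       # 82
#' table(atlas$network)["subcortical"]  # 14
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  required <- c("name", "hemisphere", "network")
  if (!all(required %in% names(df)))
    stop("atlas must have columns: ", paste(required, collapse = ", "))
  as_parcellation_atlas(df[required])
}

#' Construct/validate a parcellation atlas from a data.frame
#'
#' @param df data.frame with columns `name`, `hemisphere`, `network`.
#' @return A validated `parcellation_atlas`.
#' @export
as_parcellation_atlas <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate region names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad <- setdiff(unique(df$network), NETWORK_LABELS)
  if (length(bad))
    stop("unknown network label: ", paste(bad, collapse = ", "))
  if (!all(df$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  rownames(df) <- NULL
  class(df) <- c("parcellation_atlas", "data.frame")
  df
}

#' The bundled 82-region atlas
#'
#' 68 Desikan-Killiany cortical regions (34 per hemisphere), each assigned the
#' modal Yeo-7 network of its surface vertices, plus 7 subcortical structures
#' per hemisphere (thalamus, caudate, putamen, pallidum, hippocampus,
#' amygdala, accumbens). This static lookup makes network tagging of regional
#' results reproducible; it ships as `inst/extdata/atlas_dk82.tsv`.
#'
#' @return A `parcellation_atlas` with 82 rows.
#' @export
default_atlas <- function() {
  load_atlas(system.file("extdata", "atlas_dk82.tsv",
                         package = "connectopath", mustWork = TRUE))
}

#' Network label of a region
#'
#' @param atlas A `parcellation_atlas`.
#' @param region Region name.
#' @return One of the eight network labels.
#' @examples
#' network_of(default_atlas(), "right_supramarginal")  # "ventral_attention"
#' @export
network_of <- function(atlas, region) {
  i <- match(region, atlas$name)
  if (is.na(i)) stop("unknown region: ", region)
  atlas$network[i]
}
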