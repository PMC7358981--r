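#' Load the default-mode-network node atlas
#'
#' The default atlas lists the 26 AAL90 regions commonly taken as the nodes of
#' the default mode network (DMN): 13 homologous region pairs, interleaved so
#' that each left-hemisphere node is immediately followed by its right
#' counterpart. In AAL90, odd region indices are left-hemisphere and even
#' indices right-hemisphere; abbreviations carry a matching ".L"/".R" suffix.
#' All connectivity matrices produced by the package use this row order.
#'
#' The atlas ships as a tab-separated file so other parcellations can be
#' substituted; a replacement must provide the same four columns and satisfy
#' the same hemisphere conventions.
#'
#' @param file Path to a tab-separated atlas file with columns `aal_index`,
#'   `abbreviation`, `hemisphere` and `name`. Defaults to the packaged
#'   26-node DMN atlas.
#' @return A data frame of class `dmn_atlas`, one row per node in network
#'   row order.
#' @examples
#' atlas <- dmn_atlas()
#' nrow(atlas)                      # 26
#' table(atlas$hemisphere)          # 13 left, 13 right
#' @export
dmn_atlas <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "dmn_aal90_atlas.tsv",
                        package = "dmnph", mustWork = TRUE)
  }
  atlas <- utils::read.delim(file, stringsAsFactors = FALSE)
  required <- c("aal_index", "abbreviation", "hemisphere", "name")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0L) {
    stop("atlas file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  atlas$aal_index <- as.integer(atlas$aal_index)
  validate_atlas(atlas)
  class(atlas) <- c("dmn_atlas", "data.frame")
  atlas
}

validate_atlas <- function(atlas) {
  if (anyDuplicated(atlas$aal_index)) {
    stop("atlas AAL indices must be unique", call. = FALSE)
  }
  if (!all(atlas$hemisphere %in% c("left", "right"))) {
    stop("atlas hemisphere must be 'left' or 'right'", call. = FALSE)
  }
  odd <- atlas$aal_index %% 2L == 1L
  if (!all(odd == (atlas$hemisphere == "left"))) {
    stop("hemisphere must be 'left' exactly for odd AAL indices", call. = FALSE)
  }
  suffix <- ifelse(atlas$hemisphere == "left", "\\.L$", "\\.R$")
  ok <- mapply(grepl, suffix, atlas$abbreviation)
  if (!all(ok)) {
    stop("abbreviation suffix .L/.R must match the hemisphere column",
         call. = FALSE)
  }
  invisible(atlas)
}

#' Row positions of a hemispheric scope
#'
#' Maps a network scope (whole brain, left or right hemisphere) to the atlas
#' row positions it selects, preserving atlas order. Used to subset time
#' series and connectivity matrices for the hemispheric analyses.
#'
#' @param atlas A `dmn_atlas` data frame (see [dmn_atlas()]).
#' @param scope One of `"both"`, `"left"`, `"right"`.
#' @return Integer vector of row positions (length 26 for `"both"`, 13 for a
#'   single hemisphere with the default atlas).
#' @examples
#' length(scope_indices(dmn_atlas(), "left"))   # 13
#' @export
scope_indices <- function(atlas, scope = c("both", "left", "right")) {
  scope <- match.arg(scope)
  switch(scope,
    both  = seq_len(nrow(atlas)),
    left  = which(atlas$hemisphere == "left"),
    right = which(atlas$hemisphere == "right")
  )
}

#' Write an atlas back to its on-disk representation
#'
#' @param atlas A `dmn_atlas` data frame.
#' @param file Output path (tab-separated, header row).
#' @return `file`, invisibly.
#' @export
write_atlas <- function(atlas, file) {
  utils::write.table(atlas, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
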