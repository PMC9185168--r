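#' The 32-electrode 10-20 montage
#'
#' Channel labels of the Biosemi 32-electrode layout used by consumer-grade
#' affective-EEG recordings, in the vendor's cap order. All channel-set
#' operations in the package resolve names against this list.
#'
#' @format A character vector of 32 electrode labels.
#' @export
biosemi32_montage <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
  "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
  "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
  "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2"
)

# Region channel lists. The auditory set is the temporal-lobe group used for
# sound-driven responses; the visual set is the occipital group. F3/F4/F7/F8
# are kept in the auditory set deliberately: the method's channel grouping
# assigns them there, and the grouping is part of the method, not an
# anatomical atlas.
.brada_regions <- list(
  auditory = c("F7", "F8", "F3", "F4", "FC5", "FC6", "T7", "T8",
               "CP5", "CP6", "P7", "P8"),
  visual   = c("PO3", "PO4", "O1", "Oz", "O2")
)

#' Canonicalize channel names against the 32-channel montage
#'
#' Matching is case-insensitive; output uses the montage's canonical
#' capitalization (e.g. `"oz"` becomes `"Oz"`).
#'
#' @param names Character vector of channel labels.
#' @return Character vector of canonical labels, same length and order.
#' @keywords internal
canonical_channels <- function(names) {
  idx <- match(tolower(names), tolower(biosemi32_montage))
  if (anyNA(idx)) {
    bad <- names[is.na(idx)]
    stop("Unknown channel name(s): ", paste(bad, collapse = ", "),
         ". Channels must belong to the 32-electrode 10-20 montage.",
         call. = FALSE)
  }
  biosemi32_montage[idx]
}

#' Channel set for a brain region
#'
#' Returns the fixed, ordered channel list for one of the method's brain
#' regions. The visual region is the five occipital electrodes; the auditory
#' region is the twelve temporally-located electrodes the method groups with
#' auditory processing; `"all"` is the full 32-channel montage.
#'
#' @param region One of `"auditory"`, `"visual"`, `"all"`.
#' @return A `channel_set` object: a character vector of canonical channel
#'   names with a `region` attribute.
#' @examples
#' region_channels("visual")
#' length(region_channels("auditory"))
#' @export
region_channels <- function(region) {
  valid <- c("auditory", "visual", "all")
  if (!is.character(region) || length(region) != 1 || !(region %in% valid)) {
    stop("Unknown region ", deparse(region), "; valid regions are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  names <- if (region == "all") biosemi32_montage else .brada_regions[[region]]
  channel_set(names, region = region)
}

#' Construct a channel set
#'
#' @param names Channel labels (case-insensitive, must belong to the
#'   32-channel montage); duplicates are an error.
#' @param region Region tag: `"auditory"`, `"visual"`, `"all"` or `"custom"`.
#' @return A `channel_set` object.
#' @export
channel_set <- function(names, region = "custom") {
  names <- canonical_channels(names)
  if (anyDuplicated(names)) {
    stop("Duplicate channel names in channel set: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  structure(names, region = region, class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> region:", attr(x, "region"),
      sprintf("(%d channels)\n", length(x)))
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate the region membership of every montage channel
#'
#' @return A tibble with columns `channel` and `region` (`auditory`,
#'   `visual`, or `other`), one row per montage channel.
#' @export
montage_regions <- function() {
  region <- rep("other", length(biosemi32_montage))
  region[biosemi32_montage %in% .brada_regions$auditory] <- "auditory"
  region[biosemi32_montage %in% .brada_regions$visual] <- "visual"
  tibble::tibble(channel = biosemi32_montage, region = region)
}

#' Export the region map as plain text
#'
#' Writes one `channel<TAB>region` line per montage channel, for audit.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage_map <- function(path) {
  map <- montage_regions()
  writeLines(paste(map$channel, map$region, sep = "\t"), path)
  invisible(path)
}
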