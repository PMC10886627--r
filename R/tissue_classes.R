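#' The closed six-class tissue vocabulary
#'
#' Every label in the pipeline is one of six tissue classes: tumor (oral
#' squamous cell carcinoma), stroma, adipose tissue, muscle, squamous
#' epithelium, and glandular tissue.  The vector's order is the canonical
#' internal class order used by confusion matrices, class distributions and
#' model outputs.
#'
#' @export
TISSUE_CLASSES <- c("tumor", "stroma", "adipose", "muscle",
                    "squamous_epithelium", "glandular")

# Alias table mapping annotation-tool spellings (e.g. QuPath classification
# names such as "Squamous epithelium" or "AdiposeTissue") to canonical
# class ids.  Matching is case-insensitive after squashing spaces,
# hyphens and underscores.
.class_alias_table <- c(
  "tumor" = "tumor",
  "tumour" = "tumor",
  "stroma" = "stroma",
  "adipose" = "adipose",
  "adiposetissue" = "adipose",
  "fat" = "adipose",
  "muscle" = "muscle",
  "muscletissue" = "muscle",
  "squamousepithelium" = "squamous_epithelium",
  "epithelium" = "squamous_epithelium",
  "glandular" = "glandular",
  "glandulartissue" = "glandular",
  "gland" = "glandular"
)

#' Normalize a tissue-class name to the canonical vocabulary
#'
#' @param name character vector of class names as found in annotation files.
#' @param strict if `TRUE` (default) an unknown name is an error; otherwise
#'   unknown names map to `NA` so callers can skip them with a warning.
#' @return character vector of canonical class ids (see [TISSUE_CLASSES]).
#' @examples
#' normalize_tissue_class(c("Tumor", "Squamous epithelium"))
#' @export
normalize_tissue_class <- function(name, strict = TRUE) {
  key <- tolower(gsub("[ _-]", "", name))
  out <- unname(.class_alias_table[key])
  if (strict && anyNA(out)) {
    bad <- unique(name[is.na(out)])
    stop("unknown tissue class name(s): ", paste(bad, collapse = ", "),
         "; the vocabulary is closed over: ",
         paste(TISSUE_CLASSES, collapse = ", "))
  }
  out
}

# factor over the canonical class order (internal)
as_tissue_factor <- function(x) factor(x, levels = TISSUE_CLASSES)
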