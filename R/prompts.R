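# Random prompt pool: positioned templates (pre/mid/post) with one "{}"
# slot for the class label. During training one template is sampled
# uniformly per instance; at inference all templates are rendered per class
# and their similarities ensembled.

#' Create a prompt template
#'
#' @param position One of `"pre"`, `"mid"`, `"post"` — whether the label slot
#'   leads, sits inside, or trails the description.
#' @param text Template string containing exactly one `"{}"` slot.
#' @return A `prompt_template` object.
#' @export
prompt_template <- function(position, text) {
  position <- match.arg(position, c("pre", "mid", "post"))
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("`text` must be a non-empty string")
  n_slots <- lengths(regmatches(text, gregexpr("\\{\\}", text)))
  if (n_slots != 1L)
    stop("template must contain exactly one \"{}\" slot")
  structure(list(position = position, text = text), class = "prompt_template")
}

#' Create a prompt pool
#'
#' @param templates List of [prompt_template()] objects covering all three
#'   positions (pre, mid, post).
#' @param class_labels Ordered character vector of class label strings; the
#'   index (0-based class id) is fixed and serialized with the pool.
#' @return A `prompt_pool` object.
#' @export
prompt_pool <- function(templates, class_labels) {
  stopifnot(length(templates) >= 1L,
            all(vapply(templates, inherits, logical(1), "prompt_template")))
  pos <- vapply(templates, `[[`, character(1), "position")
  missing <- setdiff(c("pre", "mid", "post"), unique(pos))
  if (length(missing))
    stop("pool must contain at least one template per position; missing: ",
         paste(missing, collapse = ", "))
  if (length(class_labels) < 2L) stop("at least two class labels required")
  structure(list(templates = templates, class_labels = as.character(class_labels)),
            class = "prompt_pool")
}

#' Default CEUS prompt pool
#'
#' Three generic exemplars per position plus task-specific phrasings for
#' breast CEUS axillary-lymph-node prediction. Class labels are ordered
#' `("non-metastatic", "metastatic")` so the label index matches the 0/1
#' class coding.
#' @return A `prompt_pool`.
#' @export
default_prompt_pool <- function() {
  tpl <- function(p, xs) lapply(xs, prompt_template, position = p)
  templates <- c(
    tpl("pre", c(
      "{}, an action",
      "{} this is an disease",
      "{}, a video of symptom",
      "{}, a contrast enhanced ultrasound video of a breast lesion",
      "{}, axillary lymph node status on breast ceus",
      "{} breast tumor with dynamic contrast enhancement")),
    tpl("mid", c(
      "video classification of {}, a disease",
      "the disease is {}, look here",
      "Can you recognize {}? a Symptom of disease",
      "a breast lesion showing {}, on contrast enhanced ultrasound",
      "ceus perfusion pattern of {}, in a breast tumor",
      "this ultrasound clip shows {}, after microbubble injection")),
    tpl("post", c(
      "a video of action {}",
      "a sample of disease {}",
      "Human of {}",
      "a ceus video of a {} breast lesion",
      "axillary lymph nodes judged {}",
      "wash in and wash out kinetics of a {} lesion"))
  )
  prompt_pool(templates, c("non-metastatic", "metastatic"))
}

#' Render a template with a class label
#'
#' Replaces the single `"{}"` slot with `label`, verbatim.
#'
#' @param template A `prompt_template`.
#' @param label Non-empty label string.
#' @return The rendered string.
#' @examples
#' render_prompt(prompt_template("mid", "the disease is {}, look here"), "metastatic")
#' @export
render_prompt <- function(template, label) {
  stopifnot(inherits(template, "prompt_template"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string")
  sub("{}", label, template$text, fixed = TRUE)
}

#' Sample one template uniformly from the pool
#'
#' Positions are pooled: every template is equally likely. Uses (and
#' advances) R's global random number generator, so draws are reproducible
#' under `set.seed()`.
#'
#' @param pool A `prompt_pool`.
#' @return A `prompt_template`.
#' @export
sample_prompt <- function(pool) {
  stopifnot(inherits(pool, "prompt_pool"))
  n <- length(pool$templates)
  if (n == 0L) stop("empty prompt pool")
  pool$templates[[sample.int(n, 1L)]]
}

#' Rendered prompt texts for one class
#'
#' @param pool A `prompt_pool`.
#' @param class_id 0-based class id indexing `pool$class_labels`.
#' @param mode `"all"` renders every template with the class label (the
#'   inference-time prompt ensemble); `"sampled"` renders one uniformly
#'   drawn template (training).
#' @return Character vector of rendered prompts.
#' @export
class_prompt_texts <- function(pool, class_id, mode = c("all", "sampled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "prompt_pool"))
  if (class_id < 0 || class_id >= length(pool$class_labels))
    stop("invalid class id")
  label <- pool$class_labels[class_id + 1L]
  if (mode == "all") {
    vapply(pool$templates, render_prompt, character(1), label = label)
  } else {
    render_prompt(sample_prompt(pool), label)
  }
}

#' Read a prompt pool from its JSON definition file
#'
#' The file has keys `pre`, `mid`, `post` (arrays of template strings) and
#' `class_labels`.
#'
#' @param path Path to the JSON pool file.
#' @return A `prompt_pool`.
#' @export
read_prompt_pool <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  templates <- unlist(lapply(c("pre", "mid", "post"), function(p) {
    lapply(x[[p]], prompt_template, position = p)
  }), recursive = FALSE)
  prompt_pool(templates, x$class_labels)
}

#' Write a prompt pool to a JSON definition file
#'
#' @param pool A `prompt_pool`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_prompt_pool <- function(pool, path) {
  pos <- vapply(pool$templates, `[[`, character(1), "position")
  txt <- vapply(pool$templates, `[[`, character(1), "text")
  jsonlite::write_json(list(
    pre = txt[pos == "pre"], mid = txt[pos == "mid"], post = txt[pos == "post"],
    class_labels = pool$class_labels
  ), path, auto_unbox = FALSE)
  invisible(path)
}

#' Degenerate single-template pool (random prompts disabled)
#'
#' Keeps only the first template of the pool, reproducing the fixed-prompt
#' baseline configuration in which every instance uses the same template.
#'
#' @param pool A `prompt_pool`.
#' @return A `prompt_pool` containing only the pool's first template.
#' @export
fixed_prompt_pool <- function(pool) {
  stopifnot(inherits(pool, "prompt_pool"))
  out <- pool
  out$templates <- pool$templates[1L]
  out
}
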