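TEMPLATE_NAMES <- c(
  "original", "original_role", "original_instruction",
  "original_role_instruction", "few_shot"
)

#' Load a prompt template
#'
#' Templates are plain-text resources containing the placeholders
#' `[phenotype list]` and `[top k]`, each exactly once. Five templates ship
#' with the package: four zero-shot variants (`original`, `original_role`,
#' `original_instruction`, `original_role_instruction`) that differ in the
#' genetic-counselor role assignment and the use-your-trained-knowledge
#' instruction, and a `few_shot` variant carrying three worked
#' phenotype-response examples (including a nonsense-token example answered
#' "not applicable"). Additional templates can be supplied as `.txt` files
#' in a user directory.
#'
#' @param name Template name (file stem).
#' @param template_dir Optional directory searched before the packaged
#'   templates.
#' @return A `prompt_template`: a list with `name` and `body`.
#' @export
prompt_template <- function(name, template_dir = NULL) {
  path <- NULL
  if (!is.null(template_dir)) {
    candidate <- file.path(template_dir, paste0(name, ".txt"))
    if (file.exists(candidate)) path <- candidate
  }
  if (is.null(path)) {
    path <- system.file("templates", paste0(name, ".txt"), package = "genevalr")
    if (!nzchar(path)) {
      stop("Unknown prompt template: ", name, call. = FALSE)
    }
  }
  body <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
    collapse = "\n"
  )
  for (ph in c("[phenotype list]", "[top k]")) {
    n <- lengths(regmatches(body, gregexpr(ph, body, fixed = TRUE)))
    if (n != 1) {
      stop(
        "Template `", name, "` must contain `", ph, "` exactly once (found ",
        n, ")",
        call. = FALSE
      )
    }
  }
  structure(list(name = name, body = body), class = "prompt_template")
}

#' List the packaged prompt template names
#' @return Character vector of template names.
#' @export
list_templates <- function() TEMPLATE_NAMES

#' Render a prompt for a case
#'
#' Substitutes the case's phenotype input for `[phenotype list]` and the
#' task threshold for `[top k]` ("top 10" or "top 50"). Rendering is pure:
#' the same inputs always yield the same string, and no bracket placeholder
#' survives substitution.
#'
#' @param template A `prompt_template` or a template name.
#' @param case One-row cohort tibble.
#' @param input_type `"hpo"` or `"free_text"`.
#' @param k Number of genes requested; 10 and 50 are the standard
#'   challenging/easy task thresholds (other values are allowed with a
#'   warning).
#' @param template_dir Passed to [prompt_template()] when `template` is a name.
#' @return The rendered prompt string.
#' @export
render_prompt <- function(template, case, input_type = c("hpo", "free_text"),
                          k = 10, template_dir = NULL) {
  input_type <- match.arg(input_type)
  if (is.character(template)) {
    template <- prompt_template(template, template_dir = template_dir)
  }
  stopifnot(inherits(template, "prompt_template"))
  if (!k %in% c(10L, 50L)) {
    warning("k = ", k, " is outside the standard task thresholds {10, 50}",
      call. = FALSE
    )
  }
  phen <- render_phenotype_list(case, input_type)
  out <- sub("[phenotype list]", phen, template$body, fixed = TRUE)
  out <- sub("[top k]", paste0("top ", k), out, fixed = TRUE)
  out
}

#' Render the few-shot prompt for a case
#'
#' Convenience wrapper around [render_prompt()] with the packaged
#' `few_shot` template, whose body carries the three worked examples
#' (neoplasm; the seizure/hypotonia developmental profile; and a
#' nonsense-token phenotype answered "not applicable") followed by the
#' query block ending `Response:`.
#'
#' @inheritParams render_prompt
#' @return The rendered prompt string.
#' @export
render_few_shot_prompt <- function(case, input_type = c("hpo", "free_text"),
                                   k = 10) {
  render_prompt(prompt_template("few_shot"), case, input_type, k)
}
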