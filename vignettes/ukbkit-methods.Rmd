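---
title: "Methods and design notes for ukbkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ukbkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ukbkit)
```

This vignette records how the package's procedures work, which defaults
matter and why, and where the design was genuinely open.

## The fileset model

A phenotype extract is modelled as three cooperating files sharing a
stem. The `.tab` table carries one row per individual (`f.eid` plus
`f.<field>.<instance>.<array>` columns, missing values written `NA`);
the `.html` dictionary maps each UDI (`21001-0.0`) to a description and
a display type; the `.r` script declares, per data coding, a pair of
vectors of raw values (`lvl.<id>`) and labels (`lbl.<id>`) and binds raw
columns to a coding in `factor()`/`ordered()` assignment statements.

`ukb_dataset()` composes three parsers. Decisions worth knowing:

* **The coding script is parsed, never sourced.** Executing code that
  arrives inside a data bundle is an obvious injection vector, so
  extraction is a small tokenizer: `c(...)` argument lists are split at
  top-level commas with full quote and backslash-escape handling, which
  is why labels may contain commas, parentheses and escaped quotes. The
  supported grammar is exactly paired `lvl.<id>`/`lbl.<id>`
  declarations plus single-line column assignments; a length mismatch
  or an assignment referencing an undeclared coding is an error naming
  the coding id.
* **Name contraction.** Lower-case the description, collapse every
  maximal run of non-alphanumeric characters (including any non-ASCII
  byte) to one underscore, strip end underscores, append
  `_f<field>_<instance>_<array>`. The operation is idempotent on its
  own output stem, and the numeric suffix guarantees injectivity even
  when two fields share a description, so no further disambiguation is
  needed.
* **Type mapping** from dictionary display strings ("Continuous",
  "Categorical (single)", ...) to internal types is a fixed table
  (`ukb_type_map()`), extendable via argument or a two-column TSV;
  unknown strings fall back to text with a warning rather than failing,
  since dictionary vocabulary drifts between showcase releases.
* **Chunked reading.** `ukb_read_tab()` reads in chunks (default
  10,000 rows) with a contract that the result is identical for any
  chunk size; the suite checks chunk sizes 1, 7 and 100 against a
  single-chunk read. Duplicated or missing `eid`s are integrity errors,
  a header without `f.eid` is a format error, and header columns absent
  from the dictionary are kept as text with a warning.
* **Unknown coded values** (a stored code with no entry in its coding)
  are retained unchanged, appended to the factor's levels, and warned
  about — silently dropping them to `NA` would hide data problems.
* **Merging** filesets is a full outer join on `eid`; colliding column
  names keep the first occurrence and suffix later ones with their
  provenance stem. Negative or otherwise unusual `eid`s (withdrawn
  participants in real extracts) pass through unmodified; filtering
  them is left to the user.

## Demographic context

`ukb_context_summary()` cross-tabulates each categorical variable by
level × subset membership and bins each continuous variable on shared
equal-width breaks (default 20) spanning the pooled non-missing range,
so the subset and reference histograms are directly comparable. Rows
with a missing subset indicator are excluded from both groups and
counted; per variable, subset + reference + missing always equals the
dataset row count, and the tests assert this conservation on every
fixture.

The default variable panel is resolved by field code — sex (31), age at
recruitment (21022), ethnic background (21000), Townsend deprivation
index (189), employment (6142), assessment centre (54), BMI (21001) —
taking instance 0 when a field was measured repeatedly (noted in the
summary metadata); any explicit list overrides it. In `fill` mode the
plot shows, per level, `n_subset / (n_subset + n_reference)`; `stack`
and `dodge` show counts. The renderer returns the drawn table next to
the figure so tests compare numbers, never pixels.

## ICD queries

Codes are stored and matched undotted ("I74", "I251"), matching how
hospital-episode fields store them; regex anchors handle prefix
matching of subcodes. Chapter resolution reduces a code to its
three-character category, mapped to a sortable key (letter rank × 100 +
two-digit number for ICD-10; leading three digits for ICD-9) and tested
for inclusive containment in each chapter's block — `I00`, `I74`,
`I219` and `I99` all land in chapter 9.

The default stratification patterns are the WHO 2015 top three causes
of death as ICD-10 regexes: `^(I2[0-5])`, `^(I6[0-9])`,
`^(J09|J1[0-9]|J2[0-2]|P23|U04)`. These are deliberately ASCII: en-dash
ranges sometimes seen in print (`I2[0–5]`) are not valid character
classes in standard regex engines, so the package normalises to ASCII
hyphens.

Continuous reference variables are split by `ukb_quantile_groups()`:
rank-based assignment into `n_groups` (default 10) groups whose sizes
differ by at most one, ties broken by stable original order (so twenty
identical values split 10/10, not 20/0). Prevalence uses all dataset
rows as its denominator — not only individuals with hospital records —
and counts each individual once however many codes match; individuals
appearing in several diagnosis fields are deduplicated by `eid`.

Diagnosis columns are discovered by name (`icd10`/`icd9` in the
descriptive column name, which the renaming step guarantees for the
hospital-episode fields), overridable by an explicit column list. The
bundled code tables are a demo subset chosen to cover the default
patterns and the worked examples; the chapter tables are complete, and
`ukb_icd_load_codes()` swaps in a user-supplied full table.

## Genetic metadata

The sample-QC file ships headerless; `ukb_sqc_names()` returns the
bundled 68-column schema (array/batch/plate metadata, submitted and
inferred sex, heterozygosity raw and PC-corrected, QC flags, forty
principal components, phasing flags). Because that layout has drifted
between releases, a schema whose length disagrees with the observed
column count is an error reporting both numbers, and any schema file
can be substituted.

Kinship degrees use the standard KING powers-of-two bins — kinship
above 0.3536 duplicate/MZ, then first (0.1768, 0.3536], second
(0.0884, 0.1768], third (0.0442, 0.0884] — configurable since the bins
are conventional rather than physical constants. The default pruning
cutoff 0.0884 sits on the same scale (3rd-degree bound).

`ukb_samples_to_remove()` treats pruning as vertex cover: nodes are
phenotyped individuals, edges are pairs with kinship above the cutoff
and both members phenotyped. Minimum vertex cover is NP-hard, and the
goal is a maximal unrelated set rather than a certified minimum, so the
package uses greedy max-degree deletion with a lexicographic (smallest
id) tie-break. That choice buys determinism and testability: the suite
proves on random graphs of up to 12 nodes that the output is always a
cover with no gratuitous removal (every removed id covered at least
one then-uncovered edge), and that it attains the brute-force minimum
on star, path and disjoint-pair families — the dominant shapes of real
relatedness graphs at this cutoff. On adversarial graphs the greedy
result can exceed the true minimum; the suite bounds it from below but
does not claim optimality.

Writers follow each downstream tool's conventions: PLINK files carry
`FID IID` (both set to `eid` — the cohort's fam files encode no family
structure) and missing as `NA` (configurable, e.g. `-9`); BGENIE files
carry no id columns at all, so their rows must follow the genotype
sample order exactly, individuals without data are emitted as `-999`,
and passing no sample order is an error rather than a guess. A
permutation test checks the row-order contract against shuffled sample
files.

## The synthetic generator

`ukb_sim_fileset()` emits the three dialects from a single
specification and returns the ground truth it built them from, making
round-trip equality — not mere plausibility — the test criterion. The
default specification is a 1000-individual, 12-variable, 3-coding
baseline extract (sex, ethnic background, BMI at two instances, age at
recruitment, Townsend index, assessment centre, attendance date,
height, household size, two ICD-10 diagnosis array columns) with 2%
missingness; continuous fields are normal draws, categorical values
uniform over coding levels, and diagnosis codes uniform over the demo
ICD-10 table. Those choices make the fixtures exercise every dialect
feature (instances, arrays, codings with commas in labels, dates,
missingness) while remaining fast; they emulate file structure, not
biology — no realistic prevalence, linkage, missingness mechanism or
population structure — so passing tests certify the plumbing and the
counting logic, not epidemiological realism. All generators are
byte-deterministic given a seed; continuous values are written with
fixed decimal formatting so determinism holds at the byte level.

Kinship fixtures draw each pair's coefficient strictly inside a
randomly chosen degree band (margin 0.001) so the intended degree is
never ambiguous after 6-decimal formatting.

## Problem sizes and numerics

The shipped test suite and acceptance script use 1000-individual
filesets for round-trips, 100–400-row fixtures for counting oracles
(50 random repetitions), 200 random graphs of at most 12 nodes for
pruning (small enough for exact vertex-cover enumeration), and 10
permutations for writer order checks; the whole suite runs in well
under a minute. Counting checks are exact (integer equality; frequencies
compared at full double precision); round-trips compare values exactly
after the generator's own decimal formatting, avoiding
representation-dependent tolerances.

## Known limitations

* The `.r` grammar supported is the paired-vector dialect described
  above; scripts using other constructions parse as "no codings" or
  raise a format error rather than being half-interpreted.
* Greedy pruning is heuristic on dense graphs (see above).
* The bundled ICD code tables are demonstration subsets; queries
  against codes outside them return a not-found result that names the
  limitation.
* Date columns are parsed as ISO `YYYY-MM-DD` only; time-of-day fields
  are mapped to the date type's behaviour.
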