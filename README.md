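# ukbkit

Tools for working with UK-Biobank-style phenotype extracts in R.

A converted UK Biobank phenotype extract arrives as a *fileset*: a large
tab-delimited data table (`<stem>.tab`) whose columns are named by numeric
showcase field codes (`f.21001.0.0`), a script (`<stem>.r`) declaring the
integer-code-to-label mappings for categorical variables, and an HTML data
dictionary (`<stem>.html`) linking each field code to a human-readable
description. Before any analysis can start, these three files must be
cross-referenced by hand. ukbkit does that wrangling in one step and adds
the query tools an epidemiologist needs next: demographic summaries of a
subset against a reference group, ICD-9/ICD-10 diagnosis queries and
disease-frequency stratification, and genetic-metadata helpers (KING
kinship relatedness counts, phenotype-aware relatedness pruning, and
PLINK/BGENIE file preparation).

No real UK Biobank data is required anywhere: a synthetic fileset
generator (`ukb_sim_fileset()` and friends) emits all of the supported
file dialects with known ground truth, and the entire test suite runs
against it.

## The core machinery

**Column naming.** Each variable's dictionary description is contracted
to snake_case — every maximal run of non-alphanumeric characters becomes
one underscore — and suffixed `_f<field>_<index>_<array>`, where *index*
is the assessment instance and *array* the response slot. So
"Body mass index (BMI)", field 21001, instance 0, array 0 becomes
`body_mass_index_bmi_f21001_0_0`. The suffix makes names unique; the stem
makes them readable.

**Coding application.** The `.r` script is parsed textually (never
executed) for paired `lvl.<id>`/`lbl.<id>` vector declarations and the
assignments binding raw columns to coding ids; stored integer codes are
then replaced by their labels (coding 9 maps 0 → Female, 1 → Male).

**Relatedness pruning.** Given KING kinship estimates for related pairs,
`ukb_samples_to_remove()` finds a set of individuals whose removal leaves
no pair with kinship above a cutoff (default 0.0884, the 3rd-degree
bound). The removal set is a vertex cover of the above-cutoff relatedness
graph restricted to phenotyped individuals, computed by greedy max-degree
deletion with a deterministic lexicographic tie-break — exact on the
stars, paths and disjoint pairs that relatedness graphs overwhelmingly
consist of, and verified against brute-force minimum covers in the test
suite. Degree bins follow the standard KING powers-of-two thresholds
(0.3536 / 0.1768 / 0.0884 / 0.0442 for duplicate-MZ / 1st / 2nd / 3rd
degree).

## Worked example

```r
library(ukbkit)

# A synthetic fileset standing in for a real extract
sim <- ukb_sim_fileset(out_dir = "demo", spec = ukb_sim_spec(n = 1000, seed = 7))

my_data <- ukb_dataset("ukbsim", path = "demo")
names(my_data)[1:4]
#> [1] "eid"                            "sex_f31_0_0"
#> [3] "ethnic_background_f21000_0_0"   "body_mass_index_bmi_f21001_0_0"

ukb_field_lookup(my_data, field = 21001)[, c("column_name", "raw_udi")]
#> 1 body_mass_index_bmi_f21001_0_0  21001-0.0
#> 2 body_mass_index_bmi_f21001_1_0  21001-1.0

# How representative are the overweight participants?
cs <- ukb_context_summary(my_data,
                          my_data$body_mass_index_bmi_f21001_0_0 >= 25,
                          subset_label = "BMI >= 25")
cs
#> Demographic context: BMI >= 25
#>   subset n = 678 | reference n = 308 | indicator missing = 14
#>   categorical variables: 3 | continuous variables: 3
ukb_context_plot(cs, bar_position = "fill")   # $plot and the drawn $data

# ICD queries
ukb_icd_meaning("I74")
#> [1] "Arterial embolism and thrombosis"
ukb_icd_chapter("I74")
#>   code  chapter block_start block_end description
#> 1 I74         9 I00         I99       Diseases of the circulatory system
ukb_icd_prevalence(my_data, "^I2[0-5]")
#> [1] 0.274

# Disease frequency by sex, for the WHO-2015 top-3 causes of death
ukb_icd_freq_by(my_data, "sex_f31_0_0")[, c("group", "dx", "frequency")]
#>   Female  coronary_artery_disease            0.261
#>   Female  cerebrovascular_disease            0.342
#>   Female  lower_respiratory_tract_infection  0.457
#>   Male    coronary_artery_disease            0.282
#>   ...

# Relatedness: counts by degree, then prune to an unrelated subset
k <- ukb_sim_kinship("rel.txt", n_pairs = 30, seed = 7)
pairs <- ukb_read_kinship("rel.txt")
ukb_rel_count(pairs)
#>   duplicate_mz 5 | first 8 | second 5 | third 4
rm_ids <- ukb_samples_to_remove(pairs,
                                phenotyped_ids = unique(c(pairs$id1, pairs$id2)))
length(rm_ids)
#> [1] 14    # removing these leaves no pair with kinship > 0.0884
```

The prevalence above is the fraction of all 1000 individuals carrying at
least one ICD-10 code in I20–I25 (coronary artery disease) in either
diagnosis array column; each `frequency` row is the same quantity within
one level of the reference variable. (The synthetic generator draws
diagnosis codes uniformly from a small demo code table, so these
frequencies are far higher than in any real cohort — they exercise the
counting machinery, not epidemiology.)

## Scope notes

The bundled ICD chapter tables are complete; the ICD code tables are a
demonstration subset — load a full table with `ukb_icd_load_codes()`.
Downloading/decrypting raw UK Biobank bundles, kinship estimation from
genotypes, and BGEN/BED genotype payloads are out of scope.
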