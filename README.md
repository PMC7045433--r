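# mhcasefind

Case identification (computational phenotyping) of mental health and
related problems in children and young people, ages 0–24, from linked
administrative health data.

Population-scale mental-health research increasingly relies on linked
administrative collections — specialist mental-health service diagnoses
and activity (PRIMHD), publicly funded hospital discharges (NMDS),
subsidised pharmaceutical dispensings (Pharms), disability-support
referrals (Socrates), and the mortality collection — none of which alone
captures the treated population. `mhcasefind` implements a transparent,
codebook-driven method that combines all five: it is written for
epidemiologists and health-services researchers who need per-person
problem indicators and confidentialised prevalence tables from
event-level extracts, and for anyone who wants to stress-test such a
method on synthetic data with known ground truth.

## The method

Each coded event is a tuple *(person, source, date, code, code system,
rank)*. A **codebook** maps *(code system, code, source, age)* to one of
13 problem categories — anxiety, depression, emotional problems (where
anxiety and depression cannot be distinguished), bipolar disorders,
substance problems, eating problems, disruptive behaviours, psychosis,
personality disorders, sleep problems, self-harm, other mental health,
and mental health not defined. ICD-10-AM codes resolve hierarchically
(exact match, then longest declared prefix); DSM-IV codes, pharmaceutical
chemical IDs and service activity/team codes match exactly. Rules carry
integer age restrictions in 0–24 (e.g. amitriptyline counts toward
depression only from age 20, because younger dispensing is commonly for
neuropathic pain), and every rule's (category, source) pair must be
ticked in a category-by-source support matrix that validation enforces.

For a fiscal year *Y* (1 July–30 June) and resident population roster
*P* (persons aged 0–24 at 1 July, excluding those who died before the
window or were overseas throughout it), the indicator for person *i* and
category *c* is

> I<sub>ic</sub> = 1 iff at least one event of person *i* in window *Y*
> matches a rule for *c* at the person's age on the event date,

with a per-category attribution set A<sub>ic</sub> ⊆ {PRIMHD, NMDS,
PHARMS, SOCRATES, MORTALITY} recording which sources independently
triggered it. A precedence rule then sets the residual indicator
`mh_not_defined` to 0 for anyone who also has a specific problem-group
indicator (self-harm excluded). Reporting follows official NZ
confidentiality practice: every released count is randomly rounded to
base 3 (nearer multiple w.p. 2/3, farther w.p. 1/3 — unbiased), cells
with raw counts below 6 are suppressed as `S`, and 12-month rates per
100,000 use category-specific denominators (substance and psychosis
10–24, bipolar 15–24, personality 18–24, otherwise 0–24).

The shipped codebook is an **exemplar** containing the method's stated
medication-inference rules plus placeholder diagnosis rules for every
supported category–source cell; real analyses supply their own codebook
file — the method, not the list, is what the package implements.

## Worked example

Simulate a cohort with known ground truth, run the pipeline, and render
the releasable table:

```r
library(mhcasefind)

cfg   <- scenario_config(n_persons = 5000, seed = 42)
paths <- generate(cfg, "demo")                      # roster + 6 event files

roster <- read_roster("demo/roster.tsv")
pop    <- build_population(roster, "2014/15")
pop
#> <population_roster> 2014/15: 5000 members aged 0-24 at 2014-07-01
#>   0-4   5-9 10-14 15-19 20-24
#>  1024   955   982   993  1046

rules  <- load_ruleset(exemplar_codebook_path())
events <- read_event_dir("demo")
ind    <- identify(events$events, pop, roster$persons, rules, "2014/15")
nrow(ind)                                           # identified persons
#> [1] 315

rt <- render(count_table(ind, pop), seed = 1)
rt
#> Confidentialised category x source counts (RR3, suppression < 6, seed 1)
#>        category PRIMHD NMDS PHARMS SOCRATES MORTALITY total rate_per_100k
#>         anxiety     15    6     36        S              39           820
#>      depression     12    S      S        S              18           320
#>       emotional     33   12     78                       93          1840
#>         bipolar                  S                        S           147
#>       substance     30    6     48        S              66          2119
#>          eating      S                                    S            20
#>      disruptive     21    6     33        S              39           780
#>       psychosis      S    S      9                        9           265
#>     personality      S    S                               6           481
#>           sleep      6    S     18                       21           380
#>       self_harm           6                               6           140
#>        other_mh      S    S                               S            60
#>  mh_not_defined     15    S     21                       27           540
#>   sub_total_any    129   39    216        6             279          5600
#>       total_any    144   54    240        6             315          6300
```

315 of 5000 persons (a 12-month identified prevalence of 6300 per
100,000, i.e. 6.3%) carry at least one indicator; Pharms is the largest
single source, and small cells are suppressed. Because the cohort is
synthetic we can also score the pipeline against the truth:

```r
rec <- evaluate_recovery("demo/ground_truth.tsv", ind)
sum(rec$identified_true) / sum(rec$true_n)   # overall sensitivity
#> [1] 0.786
sum(rec$false_positives)                     # no noise injected -> 0
#> [1] 0
```

The remaining ~21% is the designed undercount: true cases none of whose
permitted sources captured an event.

A thin command-line wrapper is installed as `exec/mh-casefind`
(subcommands `simulate`, `identify`, `tabulate`, `codebook-validate`).

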