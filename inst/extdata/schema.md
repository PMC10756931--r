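# Input table schemas

All inputs are UTF-8 CSV with a header row (RFC-4180 quoting).

## records.csv — compliance monitoring records
| column | type | notes |
|---|---|---|
| system_id | character | must exist in inventory.csv |
| sample_date | date (YYYY-MM-DD) | calendar year drives yearly averaging |
| value | numeric | concentration in `units`; blank when nondetect |
| units | "mg/L" or "ug/L" | micro sign accepted |
| lod | numeric | record-specific limit of detection, same units |
| detected | logical | FALSE = left-censored at `lod` |
| sample_type | "treated" or "raw" | drives the yearly override rule |

## inventory.csv — water-system inventory
| column | type | notes |
|---|---|---|
| system_id | character | one row per system-county pair |
| county_id | character | must exist in counties.csv |
| population_served | integer > 0 | weight basis for county aggregation |
| source_type | "groundwater" / "surface" | surface systems sample yearly |
| region, cluster | character | closed label vocabularies |
| tribal, correctional | logical | subgroup flags |
| fluoridation_reported | logical or blank | blank = no voluntary report |
| size_category | factor (optional) | derived from population_served if absent |

## counties.csv — county covariates
| column | type | notes |
|---|---|---|
| county_id | character | unique |
| pct_hispanic, pct_nh_black, pct_aian, pct_nh_white | percent 0-100 | |
| count_hispanic, count_nh_black, count_aian, count_nh_white | persons | 100-resident restriction basis |
| population | persons | |
| density | persons per square mile | |
| svi | 0-1 | socioeconomic vulnerability index |
| pct_groundwater | percent 0-100 | share of public water from groundwater |
| public_water_population | persons | denominator of the coverage filter |

## adjacency.csv — county contiguity edge list
| column | type | notes |
|---|---|---|
| county_a, county_b | character | one row per undirected edge, no self-edges |
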