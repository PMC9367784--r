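{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cattleGHG scenario configuration",
  "description": "One breeding-model scenario for the beef-cattle life-cycle GHG inventory. All masses are kg; the canonical internal unit for annual masses is kg/a.",
  "type": "object",
  "required": ["name", "model_kind", "herd", "planting", "manure"],
  "additionalProperties": false,
  "properties": {
    "name": {"type": "string"},
    "model_kind": {
      "enum": ["EC", "non-EC"],
      "description": "EC: ecological cycle (silage feed, full manure return, no straw burning, has a feed-production process). non-EC: conventional (common corn, partial manure return, open straw burning, no feed-production process)."
    },
    "herd": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "herd_size": {"type": "number", "minimum": 0, "description": "head/a"},
        "live_weight": {"type": "number", "minimum": 0, "description": "kg"},
        "fattening_days": {"type": "number", "minimum": 0, "description": "d/a"},
        "enteric_ef": {"type": "number", "minimum": 0, "description": "kg CH4/head/a"},
        "n_excretion_rate": {"type": "number", "minimum": 0, "description": "kg N/(1000 kg live mass)/d"},
        "manure_per_head_day": {"type": "number", "minimum": 0, "description": "kg/d"}
      }
    },
    "planting": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "feed_intake_per_head_day": {"type": "number", "minimum": 0, "description": "kg/head/d"},
        "planting_area": {"type": "number", "minimum": 0, "description": "hm2"},
        "fertilizer_application_rate": {"type": "number", "minimum": 0, "description": "kg/hm2/a"},
        "n_fertilizer_share": {"type": "number", "minimum": 0, "maximum": 1},
        "compound_fertilizer_share": {"type": "number", "minimum": 0, "maximum": 1},
        "compound_n_content": {"type": "number", "minimum": 0, "maximum": 1},
        "straw_feed_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "straw_burn_fraction": {"type": "number", "minimum": 0, "maximum": 1,
          "description": "0 for EC; > 0 for non-EC; feed + burn fractions must sum to at most 1"},
        "is_silage": {"type": "boolean"}
      }
    },
    "manure": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "return_rate": {"type": "number", "minimum": 0, "maximum": 1,
          "description": "fraction of manure entering the planting system"},
        "vs_rate": {"type": "number", "minimum": 0, "description": "kg VS/(1000 kg live mass)/d"},
        "ms_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "mm_ch4_ef": {"type": "number", "minimum": 0, "description": "kg CH4/kg VS"},
        "mm_n2o_direct_ef": {"type": "number", "minimum": 0, "description": "kg N2O-N/kg N"},
        "f_gas": {"type": "number", "minimum": 0, "maximum": 1},
        "f_leach": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "factors": {
      "type": "object",
      "additionalProperties": false,
      "description": "Emission-factor set; omitted keys take the reference defaults.",
      "properties": {
        "ef_farm_corn": {"type": "number", "minimum": 0, "description": "t CO2/t corn"},
        "ef_feed_corn": {"type": "number", "minimum": 0, "description": "t CO2/t silage"},
        "ef_n_direct": {"type": "number", "minimum": 0, "description": "t N2O-N/t N"},
        "ef_n_vol_indirect": {"type": "number", "minimum": 0, "description": "t N2O-N/t N"},
        "ef_n_leach_indirect": {"type": "number", "minimum": 0, "description": "t N2O-N/t N"},
        "f_gas_fert": {"type": "number", "minimum": 0, "maximum": 1},
        "f_gas_manure": {"type": "number", "minimum": 0, "maximum": 1},
        "f_leach_soil": {"type": "number", "minimum": 0, "maximum": 1},
        "burn_combustion_factor": {"type": "number", "minimum": 0},
        "ef_burn_co2": {"type": "number", "minimum": 0, "description": "kg CO2/kg straw burned"},
        "ef_burn_ch4": {"type": "number", "minimum": 0, "description": "kg CH4/kg straw burned"},
        "ef_burn_n2o": {"type": "number", "minimum": 0, "description": "kg N2O/kg straw burned"},
        "ef_mm_idn_vol": {"type": "number", "minimum": 0, "description": "kg N2O-N/kg volatilized N"},
        "ef_mm_idn_leach": {"type": "number", "minimum": 0, "description": "kg N2O-N/kg leached N"}
      }
    },
    "gwp": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "gwp_ch4": {"type": "number", "exclusiveMinimum": 0, "default": 28},
        "gwp_n2o": {"type": "number", "exclusiveMinimum": 0, "default": 265},
        "gwp_n2o_manure_application": {"type": "number", "exclusiveMinimum": 0, "default": 273,
          "description": "used only by the as-reported (replication-mode) manure-application pathway"}
      }
    },
    "overrides": {
      "type": "object",
      "description": "Optional as-reported per-process CO2-eq overrides (kg/a), keyed by process id; applied only in replication mode.",
      "propertyNames": {
        "enum": ["corn_planting", "n_fertilizer", "manure_application", "feed_production", "straw_burning", "enteric_fermentation", "manure_management"]
      },
      "additionalProperties": {"type": "number", "minimum": 0}
    }
  }
}
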