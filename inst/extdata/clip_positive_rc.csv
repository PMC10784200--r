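cell_id,lon,lat,region,crop,yield_kg_ha,harvested_area_ha,n_fert,n_manure,n_total,pesticides,irrigation_tot,irrigation_reliant,mechanized,thz_class,mst_class,soil_class
1,0.020833333333333332,59.979166666666664,Europe,wheat,500,1000,150,0,,2,0.5,0.40000000000000002,1,T6,M4,S3
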