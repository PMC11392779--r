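level,name,species_count
family,Asteraceae,260
family,Cactaceae,114
family,Fabaceae,89
family,Solanaceae,34
family,Verbenaceae,30
family,Boraginaceae,26
family,Nolanaceae,22
family,Calceolariaceae,18
family,Chenopodiaceae,18
family,Apiaceae,15
family,Other families,225
genus,Senecio,99
genus,Adesmia,46
genus,Eriosyce,39
genus,Haplopappus,35
genus,Copiapoa,34
genus,Nolana,22
genus,Heliotropium,19
genus,Calceolaria,18
genus,Baccharis,16
genus,Atriplex,14
genus,Other genera,509
growth_form,shrub,443
growth_form,sub-shrub,243
growth_form,other,165
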