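quantity,store,value
discovered,ios,32614
discovered,android,4632
excluded_by_tagging,ios,10661
excluded_by_tagging,android,2180
clustered,ios,21953
clustered,android,2452
clusters_total,all,245
clusters_uninformative,all,70
apps_uninformative,all,6426
unrated,ios,16631
unrated,android,1039
rated_lt10,ios,17860
rated_lt10,android,1867
rated_gt1000,ios,302
rated_gt1000,android,38
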