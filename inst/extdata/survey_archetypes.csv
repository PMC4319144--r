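archetype,descriptor,specificity,leaks,change,loss,value,clusters,apps
1,Casual Tools,standard,none,none,none,none,9,786
2,Common Knowledge Providers,standard,none,low,none,none,58,5603
3,Treatment Guides,standard,none,high,none,none,21,2074
4,Fitness Ad-Hoc Tools,nonstandard,low,low,none,low,7,216
5,Fitness Trackers,nonstandard,low,low,low,low,21,4602
6,Treatment Support Tools,medical,low,high,none,low,13,570
7,Intimate Ad-Hoc Tools,medical,high,low,none,low,3,60
8,State of Health Tests,medical,high,low,none,high,4,500
9,Intimate Trackers,medical,high,low,low,low,4,660
10,Health Monitors,medical,high,high,none,high,3,240
11,Treatment Reminders,medical,high,high,low,high,7,570
12,Health Records,medical,high,high,high,high,25,2098
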