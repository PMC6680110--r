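state,zone,is_subtotal,total_population_million,counselling,supplementation,micronutrient_deworming,health,cash_transfers,malaria_endemic
Indo-gangetic plains,Indo-gangetic plains,1,427.7,108.3,903.9,90.6,102.1,1197.1,0
Uttar Pradesh,Indo-gangetic plains,0,199.6,51.4,420.8,42.7,32.5,616.9,0
Bihar,Indo-gangetic plains,0,103.8,30.1,266.5,25.5,33.9,324.0,0
West Bengal,Indo-gangetic plains,0,91.3,17.7,140.7,15.0,17.8,164.2,1
Jharkhand,Indo-gangetic plains,0,33.0,9.0,75.8,7.4,17.9,91.9,1
Central states,Central states,1,252.5,60.8,475.2,46.7,62.0,587.1,0
Madhya Pradesh,Central states,0,72.6,20.1,162.4,15.3,29.2,216.8,0
Maharashtra,Central states,0,112.4,24.3,186.2,18.7,14.9,207.2,0
Chhattisgarh,Central states,0,25.5,6.9,52.8,5.2,7.8,70.9,1
Odisha,Central states,0,41.9,9.5,73.8,7.4,10.1,92.2,1
Western,Western,1,182.1,45.3,356.9,35.1,31.4,454.8,0
Rajasthan,Western,0,68.6,19.2,152.6,14.9,16.6,200.6,0
Gujarat,Western,0,60.4,14.0,113.8,11.1,9.8,143.3,0
Haryana,Western,0,25.4,6.5,49.0,4.8,3.6,61.6,0
Punjab,Western,0,27.7,5.6,41.6,4.3,1.4,49.3,0
Southern,Southern,1,252.8,50.0,375.7,38.8,33.2,464.5,0
Andhra Pradesh,Southern,0,84.7,16.6,123.1,12.9,6.6,160.5,0
Karnataka,Southern,0,61.1,13.1,101.7,10.2,9.1,126.8,0
Tamil Nadu,Southern,0,72.1,13.8,103.1,10.7,14.3,123.8,0
Kerala,Southern,0,33.4,6.3,45.7,4.8,3.0,51.3,0
Goa,Southern,0,1.5,0.3,2.0,0.2,0.2,2.0,0
Northern,Northern,1,29.5,7.4,56.2,5.8,4.5,58.8,0
Jammu and Kashmir,Northern,0,12.5,3.6,26.9,2.8,1.9,25.2,0
Uttaranchal,Northern,0,10.1,2.4,18.4,1.9,1.5,21.3,0
Himachal Pradesh,Northern,0,6.9,1.4,10.9,1.1,1.1,12.3,0
North eastern,North eastern,1,44.5,11.2,90.0,9.1,13.1,104.2,0
Meghalaya,North eastern,0,3.0,1.1,8.6,0.8,2.9,8.0,1
Tripura,North eastern,0,3.7,0.8,6.1,0.6,1.1,5.9,1
Manipur,North eastern,0,2.7,0.6,4.5,0.5,0.4,4.4,1
Nagaland,North eastern,0,2.0,0.4,3.5,0.4,0.5,3.4,1
Arunachal Pradesh,North eastern,0,1.4,0.3,2.9,0.3,0.4,3.1,1
Assam,North eastern,0,31.2,7.9,63.7,6.4,7.7,78.2,1
Sikkim,North eastern,0,0.6,0.1,0.8,0.1,0.1,1.1,0
Union territories,Union territories,1,21.2,4.6,35.3,3.6,3.8,41.0,0
Delhi,Union territories,0,16.8,3.6,27.4,2.8,3.0,32.5,0
Puducherry,Union territories,0,1.2,0.3,2.0,0.2,0.2,2.3,0
Mizoram,Union territories,0,1.1,0.3,2.4,0.2,0.2,2.0,1
Chandigarh,Union territories,0,1.1,0.2,1.6,0.2,0.2,1.8,0
Dadra and Nagar Haveli,Union territories,0,0.3,0.1,0.9,0.1,0.1,1.1,0
Andaman and Nicobar Islands,Union territories,0,0.4,0.1,0.6,0.1,0.1,0.6,1
Daman and Diu,Union territories,0,0.2,0.1,0.4,0.0,0.0,0.5,0
Lakshadweep,Union territories,0,0.1,0.0,0.1,0.0,0.0,0.1,0
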