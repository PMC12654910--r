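name,financial_cost,required_knowledge,ease_of_use,customizability
Tableau,2 and Free,None,5,4
Dundas BI,1,None,4,1
Jupyter/Python,Free,"Coding principles, Matplotlib, Seaborn, etc.",1,2
Zoho Reports,1 and 3,None,5,2
Google Charts,Free,Javascript syntax,5,2
Visual.ly,Requires a quote,Unknown,5,1
RAW,Free,None,3,2
IBM Watson,Free and 3,None,4,3
Sisense,Requires a quote,None,4,3
Plotly,Free,Python coding Language,1,3
Data Wrapper,Free and 4,None,5,1
Highcharts,1,None,5,4
FusionCharts,1 and 3,Javascript,5,4
Power BI,1,None,5,2
QlikView,1,None,4,2
Infogram,Free and 1,None,4,1
ChartBlocks,Free,None,4,3
D3.js,Free,Javascript,1,2
Chart.js,Free,HTML,1,2
Grafana,Free,None,3,2
Chartist.js,Free,None,2,1
Sigma.js,Free,Javascript,1,1
Polymaps,Free,Javascript,2,1
Microsoft Excel,1,None,4,3
Google Sheets,Free,None,4,2
MATLAB,2,Basic coding Principles,2,5
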